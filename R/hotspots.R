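#' Regional recording hotspots
#'
#' EEG electrodes are grouped into eight regional "hotspots" (frontal,
#' parietal, temporal, occipital; left = ipsilateral to a left-M1
#' stimulation site, right = contralateral) whose averaged signal is the
#' unit of all downstream analysis.
#'
#' The temporal-left group is `CP5, CP3, FC5`; source listings sometimes
#' print "CF5", which does not exist in the extended 10-20 system and is
#' taken here as a typo for FC5 (the mirror of FC6 on the right).
#'
#' @return Named list mapping hotspot label to a character vector of
#'   10-20-system electrode labels. The eight sets are pairwise disjoint.
#' @examples
#' default_hotspot_map()$parietal_left
#' @export
default_hotspot_map <- function() {
  list(
    frontal_left   = c("F3", "F5"),
    frontal_right  = c("F4", "F6"),
    parietal_left  = c("C3", "C5", "CP1"),
    parietal_right = c("C4", "C6", "CP2"),
    temporal_left  = c("CP5", "CP3", "FC5"),
    temporal_right = c("CP6", "CP4", "FC6"),
    occipital_left  = c("O1", "PO3"),
    occipital_right = c("O2", "PO4")
  )
}

#' Validate a hotspot map
#'
#' @param map named list of electrode-label character vectors.
#' @return `map`, invisibly, after checking that every hotspot is non-empty
#'   and that electrode sets are pairwise disjoint.
#' @export
validate_hotspot_map <- function(map) {
  if (!is.list(map) || is.null(names(map)) || any(!nzchar(names(map))))
    stop("hotspot map must be a named list")
  if (any(lengths(map) == 0L))
    stop("every hotspot must contain at least one electrode")
  all_e <- unlist(map, use.names = FALSE)
  if (anyDuplicated(all_e))
    stop("electrode sets must be pairwise disjoint; duplicated: ",
         paste(unique(all_e[duplicated(all_e)]), collapse = ", "))
  invisible(map)
}

# hotspot label for each electrode, given a map
electrode_hotspot <- function(map) {
  setNames(rep(names(map), lengths(map)), unlist(map, use.names = FALSE))
}
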
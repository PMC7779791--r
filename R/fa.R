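#' ROI mean fractional anisotropy with FA threshold
#'
#' Reduces voxel-level FA values with parallel ROI labels to per-ROI mean
#' FA, averaging only voxels with `FA > threshold` (strictly greater,
#' default 0.2 — the usual white-matter mask). An ROI with no qualifying
#' voxel yields `NA` with `n_voxels_used = 0`, never a silent 0.
#'
#' @param fa_voxels numeric vector of voxel FA values in \[0, 1\].
#' @param roi_labels parallel character/factor vector of ROI labels.
#' @param threshold FA mask threshold, default 0.2.
#' @param subject_id optional id stamped into the output rows.
#' @return data.frame (`subject_id`, `roi`, `mean_fa`, `n_voxels_used`),
#'   one row per ROI present in `roi_labels`.
#' @export
roi_mean_fa <- function(fa_voxels, roi_labels, threshold = 0.2,
                        subject_id = NA_character_) {
  if (length(fa_voxels) != length(roi_labels))
    stop("fa_voxels and roi_labels must have equal length")
  bad <- sum(!is.finite(fa_voxels) | fa_voxels < 0 | fa_voxels > 1)
  if (bad > 0)
    stop(bad, " voxel FA value(s) outside [0, 1]")
  rois <- unique(as.character(roi_labels))
  keep <- fa_voxels > threshold
  out <- lapply(rois, function(r) {
    sel <- roi_labels == r & keep
    n <- sum(sel)
    data.frame(subject_id = subject_id, roi = r,
               mean_fa = if (n > 0) mean(fa_voxels[sel]) else NA_real_,
               n_voxels_used = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
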
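# Plain-text serialisation for every container. The epoch container is a
# delimited table (one row per subject/condition/electrode/epoch, samples
# as columns) plus a JSON metadata sidecar; all tabular outputs are TSV
# with a header row. Text-only keeps artifacts portable and diffable.

#' Write / read an epoch container
#'
#' `write_epoch_set` stores `<prefix>.tsv` (id columns `subject`,
#' `condition`, `electrode`, `epoch`, `retained`, then one column per time
#' sample) and `<prefix>.json` (time axis, sampling rate, subjects,
#' groups, conditions, electrodes). `read_epoch_set` restores the
#' [epoch_set] exactly (up to text-format rounding of amplitudes).
#'
#' @param epochs an [epoch_set].
#' @param prefix file path without extension.
#' @return `write_epoch_set`: the prefix, invisibly. `read_epoch_set`:
#'   an [epoch_set].
#' @export
write_epoch_set <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$amplitude)
  # rows ordered epoch-fastest to match array reshaping on read
  grid <- expand.grid(subject = epochs$subjects,
                      condition = epochs$conditions,
                      electrode = epochs$electrodes,
                      epoch = seq_len(d[4]),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- matrix(epochs$amplitude, nrow = prod(d[1:4]), ncol = d[5])
  tab <- data.table::data.table(grid,
                                retained = as.vector(epochs$retained))
  samp <- data.table::as.data.table(m)
  data.table::setnames(samp, paste0("s", seq_len(d[5])))
  data.table::fwrite(cbind(tab, samp), paste0(prefix, ".tsv"), sep = "\t")
  meta <- list(time_ms = epochs$time_ms,
               sampling_rate = epochs$sampling_rate,
               subjects = epochs$subjects,
               groups = as.list(epochs$groups),
               conditions = epochs$conditions,
               electrodes = epochs$electrodes)
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(prefix) {
  meta <- jsonlite::fromJSON(paste0(prefix, ".json"), simplifyVector = TRUE)
  tab <- data.table::fread(paste0(prefix, ".tsv"), sep = "\t")
  d <- c(length(meta$subjects), length(meta$conditions),
         length(meta$electrodes), max(tab$epoch), length(meta$time_ms))
  scols <- paste0("s", seq_len(d[5]))
  amp <- array(as.matrix(tab[, scols, with = FALSE]), d)
  retained <- array(tab$retained, d[1:4])
  epoch_set(amp, meta$time_ms, meta$sampling_rate, meta$subjects,
            unlist(meta$groups), meta$conditions, meta$electrodes, retained)
}

#' Long-table form of a hotspot TEP set
#'
#' `tep_table` flattens a [hotspot_tep] to a data.frame (`subject_id`,
#' `group`, `condition`, `hotspot`, `n_epochs_retained`, `time_ms`,
#' `amplitude`); `tep_from_table` inverts it, inferring the sampling rate
#' from the grid spacing.
#'
#' @param tep a [hotspot_tep].
#' @return `tep_table`: a data.frame; `tep_from_table`: a [hotspot_tep].
#' @export
tep_table <- function(tep) {
  stopifnot(inherits(tep, "hotspot_tep"))
  d <- dim(tep$amplitude)
  grid <- expand.grid(subject_id = tep$subjects,
                      condition = tep$conditions,
                      hotspot = tep$hotspots,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(
    subject_id = rep(grid$subject_id, times = d[4]),
    group = unname(tep$groups[rep(grid$subject_id, times = d[4])]),
    condition = rep(grid$condition, times = d[4]),
    hotspot = rep(grid$hotspot, times = d[4]),
    n_epochs_retained = rep(as.vector(tep$n_epochs_retained), times = d[4]),
    time_ms = rep(tep$time_ms, each = nrow(grid)),
    amplitude = as.vector(tep$amplitude),
    stringsAsFactors = FALSE)
}

#' @rdname tep_table
#' @param tab a data.frame in `tep_table` layout.
#' @export
tep_from_table <- function(tab) {
  subjects <- unique(tab$subject_id)
  conditions <- unique(tab$condition)
  hotspots <- unique(tab$hotspot)
  time_ms <- sort(unique(tab$time_ms))
  d <- c(length(subjects), length(conditions), length(hotspots),
         length(time_ms))
  amp <- array(NA_real_, d)
  idx <- cbind(match(tab$subject_id, subjects),
               match(tab$condition, conditions),
               match(tab$hotspot, hotspots),
               match(tab$time_ms, time_ms))
  amp[idx] <- tab$amplitude
  nret <- array(NA_integer_, d[1:3])
  nret[idx[, 1:3]] <- tab$n_epochs_retained
  groups <- tab$group[match(subjects, tab$subject_id)]
  sr <- 1000 / stats::median(diff(time_ms))
  hotspot_tep(amp, time_ms, subjects, groups, conditions, hotspots,
              nret, sr)
}

#' Tabular TSV writers and readers
#'
#' Thin wrappers over [data.table::fwrite()] / [data.table::fread()] used
#' for every delimited artifact (feature tables, FA tables, comparison
#' tables, rejection logs) so all stages agree on the format.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `write_table_tsv`: `path`, invisibly; `read_table_tsv`: a
#'   data.frame.
#' @export
write_table_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Write / read a normative template
#'
#' Waveforms as a TSV (`hotspot`, `time_ms`, `amplitude`) plus a JSON
#' sidecar carrying provenance (reference subject ids, age band,
#' condition), which the leakage guard relies on.
#'
#' @param template a `tep_template`.
#' @param prefix file path without extension.
#' @export
write_template <- function(template, prefix) {
  stopifnot(inherits(template, "tep_template"))
  tab <- data.frame(
    hotspot = rep(template$hotspots, each = length(template$time_ms)),
    time_ms = rep(template$time_ms, times = length(template$hotspots)),
    amplitude = as.vector(t(template$waveforms)),
    stringsAsFactors = FALSE)
  write_table_tsv(tab, paste0(prefix, ".tsv"))
  jsonlite::write_json(
    list(reference_subjects = template$reference_subjects,
         age_band = template$age_band, condition = template$condition),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_template
#' @export
read_template <- function(prefix) {
  meta <- jsonlite::fromJSON(paste0(prefix, ".json"), simplifyVector = TRUE)
  tab <- read_table_tsv(paste0(prefix, ".tsv"))
  hotspots <- unique(tab$hotspot)
  time_ms <- sort(unique(tab$time_ms))
  waves <- matrix(NA_real_, length(hotspots), length(time_ms),
                  dimnames = list(hotspots, NULL))
  waves[cbind(match(tab$hotspot, hotspots), match(tab$time_ms, time_ms))] <-
    tab$amplitude
  structure(list(waveforms = waves, time_ms = time_ms, hotspots = hotspots,
                 reference_subjects = meta$reference_subjects,
                 age_band = meta$age_band, condition = meta$condition),
            class = "tep_template")
}
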
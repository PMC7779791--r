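#' Least-squares slope of a TEP segment
#'
#' Ordinary least-squares slope of amplitude against time over the samples
#' with `t0 <= t <= t1` (inclusive). The early-phase deflection (EPD) is
#' the slope over 60-100 ms of the single-pulse TEP; the late-phase
#' deflection (LPD) the slope over 100-180 ms.
#'
#' @param amplitude numeric waveform, uV.
#' @param time_ms matching time axis, ms.
#' @param t0,t1 window bounds, ms; at least 3 samples must fall inside.
#' @return slope in uV/ms.
#' @export
compute_slope <- function(amplitude, time_ms, t0, t1) {
  stopifnot(length(amplitude) == length(time_ms), t0 < t1)
  idx <- time_ms >= t0 & time_ms <= t1
  if (sum(idx) < 3) stop("fewer than 3 samples in slope window")
  unname(lm.fit(cbind(1, time_ms[idx]), amplitude[idx])$coefficients[2])
}

#' Waveform adherence (WFA)
#'
#' Similarity of a subject's full-window TEP to the normative healthy
#' template, operationalised as the Pearson correlation coefficient over
#' the shared 20-300 ms grid (scale- and offset-invariant; cosine
#' similarity is available as an alternative metric). A zero-variance
#' input makes the measure undefined and returns `NA` rather than a
#' silent 0.
#'
#' @param amplitude subject TEP on the analysis grid.
#' @param template normative waveform on the identical grid.
#' @param metric `"pearson"` (default) or `"cosine"`.
#' @return unitless value in \[-1, 1\], or `NA` if undefined.
#' @export
compute_wfa <- function(amplitude, template, metric = c("pearson", "cosine")) {
  metric <- match.arg(metric)
  stopifnot(length(amplitude) == length(template))
  if (metric == "pearson") {
    if (sd(amplitude) == 0 || sd(template) == 0) return(NA_real_)
    cor(amplitude, template)
  } else {
    na <- sqrt(sum(amplitude^2)); nb <- sqrt(sum(template^2))
    if (na == 0 || nb == 0) return(NA_real_)
    sum(amplitude * template) / (na * nb)
  }
}

#' Mean field potential (MFP) of a TEP window
#'
#' Scalar magnitude summary: the mean rectified amplitude over the
#' analysis window, `mean(|amplitude|)`, always >= 0. (A cross-electrode
#' global-field-power variant is incompatible with the per-hotspot
#' plasticity index and is deliberately not offered.)
#'
#' @param amplitude TEP on the analysis grid, uV.
#' @return MFP in uV.
#' @export
compute_mfp <- function(amplitude) mean(abs(amplitude))

#' Short-term plasticity index (STP)
#'
#' Normalised contrast of the single-pulse and 1 Hz inhibitory-protocol
#' mean field potentials: `(MFP_single - MFP_i) / (MFP_single + MFP_i)`.
#' Positive values mean the inhibitory protocol suppressed the response.
#'
#' @param mfp_single,mfp_i non-negative MFP values, uV.
#' @return unitless value in \[-1, 1\]; `NA` if both inputs are 0.
#' @export
compute_stp <- function(mfp_single, mfp_i) {
  stopifnot(mfp_single >= 0, mfp_i >= 0)
  if (mfp_single + mfp_i == 0) return(NA_real_)
  (mfp_single - mfp_i) / (mfp_single + mfp_i)
}

#' Build a normative TEP template from healthy reference subjects
#'
#' Pointwise mean of the single-pulse hotspot TEPs across reference
#' subjects. The reference ids are stored as provenance and must stay
#' disjoint from any evaluated subject: [delphi_features()] hard-errors on
#' overlap (leakage guard).
#'
#' @param tep a [hotspot_tep] holding the reference subjects.
#' @param subjects reference subject ids (default: all in `tep`); >= 5
#'   required.
#' @param age_band free-text tag naming the normative band.
#' @param condition protocol used for the template, default `"single"`.
#' @return object of class `tep_template`: per-hotspot mean waveforms on
#'   the analysis grid plus provenance.
#' @export
build_template <- function(tep, subjects = NULL, age_band = "adult",
                           condition = "single") {
  stopifnot(inherits(tep, "hotspot_tep"))
  if (is.null(subjects)) subjects <- tep$subjects
  if (length(subjects) < 5)
    stop("a normative template needs at least 5 reference subjects")
  missing <- setdiff(subjects, tep$subjects)
  if (length(missing)) stop("unknown reference subjects: ",
                            paste(missing, collapse = ", "))
  si <- match(subjects, tep$subjects)
  ci <- match(condition, tep$conditions)
  if (is.na(ci)) stop("condition ", condition, " not present")
  # mean over subjects -> [hotspot x time]
  waves <- apply(tep$amplitude[si, ci, , , drop = FALSE], c(3, 4), mean)
  dimnames(waves) <- list(tep$hotspots, NULL)
  structure(list(waveforms = waves, time_ms = tep$time_ms,
                 hotspots = tep$hotspots, reference_subjects = subjects,
                 age_band = age_band, condition = condition),
            class = "tep_template")
}

#' @export
print.tep_template <- function(x, ...) {
  cat(sprintf("<tep_template> %d hotspots, %d samples, %d reference subjects (band: %s)\n",
              length(x$hotspots), length(x$time_ms),
              length(x$reference_subjects), x$age_band))
  invisible(x)
}

#' Extract the four DELPHI output measures per subject and hotspot
#'
#' For every (subject, hotspot): EPD and LPD (OLS slopes of the
#' single-pulse TEP over 60-100 and 100-180 ms), WFA (adherence of the
#' single-pulse TEP to the normative template), MFP of the single-pulse
#' and inhibitory responses, and the STP index. All four headline measures
#' are computed from hotspot-averaged waveforms on the 20-300 ms grid.
#'
#' @param tep a [hotspot_tep] with conditions `single` and `inhibitory`.
#' @param template a `tep_template` built from subjects disjoint from
#'   those in `tep`; overlap is a hard error (information leakage).
#' @param wfa_metric passed to [compute_wfa()].
#' @param epd_window,lpd_window slope windows, ms.
#' @return data.frame (`subject_id`, `group`, `hotspot`, `epd`, `lpd`,
#'   `wfa`, `mfp_single`, `mfp_i`, `stp`).
#' @export
delphi_features <- function(tep, template, wfa_metric = "pearson",
                            epd_window = c(60, 100),
                            lpd_window = c(100, 180)) {
  stopifnot(inherits(tep, "hotspot_tep"), inherits(template, "tep_template"))
  leaked <- intersect(tep$subjects, template$reference_subjects)
  if (length(leaked))
    stop("template leakage: reference subjects also under evaluation: ",
         paste(leaked, collapse = ", "))
  if (!all(c("single", "inhibitory") %in% tep$conditions))
    stop("both 'single' and 'inhibitory' conditions are required")
  if (length(tep$time_ms) != length(template$time_ms) ||
      any(abs(tep$time_ms - template$time_ms) > 1e-9))
    stop("template grid does not match the TEP grid")
  if (!identical(sort(tep$hotspots), sort(template$hotspots)))
    stop("template hotspots do not match the TEP hotspots")
  ci_s <- match("single", tep$conditions)
  ci_i <- match("inhibitory", tep$conditions)
  rows <- expand.grid(subject_id = tep$subjects, hotspot = tep$hotspots,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(rows)
  epd <- lpd <- wfa <- mfp_s <- mfp_i <- stp <- numeric(n)
  for (r in seq_len(n)) {
    si <- match(rows$subject_id[r], tep$subjects)
    hi <- match(rows$hotspot[r], tep$hotspots)
    ws <- tep$amplitude[si, ci_s, hi, ]
    wi <- tep$amplitude[si, ci_i, hi, ]
    epd[r] <- compute_slope(ws, tep$time_ms, epd_window[1], epd_window[2])
    lpd[r] <- compute_slope(ws, tep$time_ms, lpd_window[1], lpd_window[2])
    wfa[r] <- compute_wfa(ws, template$waveforms[rows$hotspot[r], ],
                          metric = wfa_metric)
    mfp_s[r] <- compute_mfp(ws)
    mfp_i[r] <- compute_mfp(wi)
    stp[r] <- compute_stp(mfp_s[r], mfp_i[r])
  }
  data.frame(subject_id = rows$subject_id,
             group = unname(tep$groups[rows$subject_id]),
             hotspot = rows$hotspot,
             epd = epd, lpd = lpd, wfa = wfa,
             mfp_single = mfp_s, mfp_i = mfp_i, stp = stp,
             stringsAsFactors = FALSE)
}

#' Assemble the classifier/regression feature matrix
#'
#' Fixed hotspot-major, measure-minor ordering: for each requested hotspot
#' the four measures (EPD, LPD, WFA, STP) in that order — with the default
#' four proximal hotspots this is a 16-value vector per subject. Missing
#' cells are imputed by the cohort median of the same (hotspot, measure)
#' column and logged; a subject missing more than 25% of cells is dropped
#' with a log entry.
#'
#' @param features data.frame from [delphi_features()].
#' @param hotspots hotspots to include; default the four proximal ones
#'   (left/right temporal and parietal, closest to the stimulation site).
#' @param measures measure columns, default `c("epd","lpd","wfa","stp")`.
#' @return numeric matrix `[subject x (hotspot x measure)]` with subject
#'   ids as rownames and attributes `imputed` (data.frame log) and
#'   `dropped` (character ids).
#' @export
build_feature_vector <- function(features,
                                 hotspots = c("temporal_left", "temporal_right",
                                              "parietal_left", "parietal_right"),
                                 measures = c("epd", "lpd", "wfa", "stp")) {
  missing_h <- setdiff(hotspots, unique(features$hotspot))
  if (length(missing_h)) stop("hotspots absent from the feature table: ",
                              paste(missing_h, collapse = ", "))
  subj <- unique(features$subject_id)
  cols <- as.vector(t(outer(hotspots, measures, paste, sep = ".")))
  X <- matrix(NA_real_, length(subj), length(cols),
              dimnames = list(subj, cols))
  for (h in hotspots) {
    sel <- features$hotspot == h
    ri <- match(features$subject_id[sel], subj)
    for (m in measures)
      X[ri, paste(h, m, sep = ".")] <- features[[m]][sel]
  }
  frac_missing <- rowMeans(is.na(X))
  dropped <- rownames(X)[frac_missing > 0.25]
  X <- X[frac_missing <= 0.25, , drop = FALSE]
  imputed <- data.frame(subject_id = character(), column = character(),
                        value = numeric(), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(X))) {
    na_i <- which(is.na(X[, j]))
    if (length(na_i)) {
      med <- median(X[, j], na.rm = TRUE)
      X[na_i, j] <- med
      imputed <- rbind(imputed, data.frame(
        subject_id = rownames(X)[na_i], column = colnames(X)[j],
        value = med, stringsAsFactors = FALSE))
    }
  }
  attr(X, "imputed") <- imputed
  attr(X, "dropped") <- dropped
  X
}
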
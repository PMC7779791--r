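#' Epoched-EEG container
#'
#' Holds one cohort's raw epochs as a dense 5-d array
#' `[subject, condition, electrode, epoch, time]` (uV), together with the
#' time axis (ms relative to the TMS pulse at 0), sampling rate, group
#' labels, and a logical `retained` array `[subject, condition, electrode,
#' epoch]` that artifact rejection flips instead of dropping data, so
#' epoch bookkeeping (`retained + rejected = recorded`) holds by
#' construction.
#'
#' @param amplitude 5-d numeric array as above.
#' @param time_ms strictly increasing, uniformly spaced time axis.
#' @param sampling_rate Hz.
#' @param subjects,groups subject ids and their `healthy`/`injured` labels.
#' @param conditions stimulation protocols, e.g. `c("single", "inhibitory")`.
#' @param electrodes 10-20-system labels.
#' @param retained optional logical array; defaults to all `TRUE`.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(amplitude, time_ms, sampling_rate, subjects, groups,
                      conditions, electrodes, retained = NULL) {
  d <- dim(amplitude)
  stopifnot(length(d) == 5L,
            d[1] == length(subjects), d[2] == length(conditions),
            d[3] == length(electrodes), d[5] == length(time_ms),
            length(groups) == length(subjects))
  dt <- diff(time_ms)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9)
    stop("time axis must be strictly increasing with uniform spacing")
  if (abs(dt[1] - 1000 / sampling_rate) > 1e-9)
    stop("time spacing must equal 1000/sampling_rate ms")
  if (is.null(retained))
    retained <- array(TRUE, d[1:4])
  stopifnot(identical(dim(retained), d[1:4]))
  dimnames(amplitude) <- list(subjects, conditions, electrodes, NULL, NULL)
  dimnames(retained) <- list(subjects, conditions, electrodes, NULL)
  structure(list(amplitude = amplitude, time_ms = time_ms,
                 sampling_rate = sampling_rate, subjects = subjects,
                 groups = setNames(as.character(groups), subjects),
                 conditions = conditions, electrodes = electrodes,
                 retained = retained),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$amplitude)
  cat(sprintf(
    "<epoch_set> %d subjects x %d conditions x %d electrodes x %d epochs x %d samples\n",
    d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  time [%g, %g] ms @ %g Hz; retained %d/%d epochs\n",
              min(x$time_ms), max(x$time_ms), x$sampling_rate,
              sum(x$retained), length(x$retained)))
  invisible(x)
}

# recording time axis for a config
time_axis <- function(cfg) {
  seq(-cfg$pre_stim_ms, cfg$post_stim_ms, by = 1000 / cfg$sampling_rate)
}

#' Deterministic TEP component sum
#'
#' The noise-free TEP model: a sum of Gaussian-windowed peaks,
#' `sum_k amplitude_k * exp(-(t - latency_k)^2 / (2 * width_k^2))`.
#'
#' @param component_params component table, see [default_components()].
#' @param time_ms evaluation grid (ms).
#' @return numeric vector of amplitudes (uV).
#' @export
tep_component_sum <- function(component_params, time_ms) {
  cp <- component_params
  w <- numeric(length(time_ms))
  for (k in seq_len(nrow(cp)))
    w <- w + cp$amplitude[k] *
      exp(-(time_ms - cp$latency[k])^2 / (2 * cp$width[k]^2))
  w
}

# "pink-ish" noise: AR(1) with coefficient 0.95 plus white noise, scaled so
# the per-sample marginal sd equals noise_sd. A burn-in absorbs the AR
# startup transient. Returns a [n_time x n_series] matrix.
sim_noise <- function(n_time, n_series, noise_sd, ar_coef = 0.95,
                      burn_in = 200L) {
  if (noise_sd <= 0) return(matrix(0, n_time, n_series))
  n_tot <- n_time + burn_in
  innov <- matrix(rnorm(n_tot * n_series), n_tot, n_series)
  ar <- stats::filter(innov, filter = ar_coef, method = "recursive")
  ar <- ar / sqrt(1 / (1 - ar_coef^2))        # unit marginal sd
  white <- matrix(rnorm(n_tot * n_series), n_tot, n_series)
  z <- (ar + white) / sqrt(2) * noise_sd
  matrix(z[(burn_in + 1):n_tot, ], n_time, n_series)
}

# effective inhibitory-condition amplitude factor: healthy networks show a
# suppressed 1 Hz response (factor pf < 1); injury flattens the contrast
# toward 1.
effective_plasticity <- function(severity, pf, attenuation) {
  pf + (1 - pf) * pmin(1, attenuation * severity)
}

#' Simulate a single TEP waveform
#'
#' One epoch's waveform for a given injury severity, stimulation condition
#' and hotspot proximity weight: the deterministic component sum with
#' injury-dependent suppression and delay, plus seeded pink-ish noise.
#' Injury scales every component amplitude by
#' `max(0, 1 - severity * proximity_weight)` and delays latencies by
#' `severity * 20` ms; the inhibitory condition additionally scales
#' amplitudes by the effective plasticity factor.
#'
#' @param severity injury severity in \[0, 1\].
#' @param condition `"single"` or `"inhibitory"`.
#' @param proximity_weight hotspot-specific injury scaling.
#' @param component_params component table, see [default_components()].
#' @param time_ms evaluation grid (ms).
#' @param noise_sd per-sample noise sd (uV); 0 gives the deterministic part.
#' @param plasticity_factor_healthy,plasticity_attenuation see [sim_config()].
#' @return numeric waveform (uV) on `time_ms`.
#' @export
simulate_tep_waveform <- function(severity, condition = c("single", "inhibitory"),
                                  proximity_weight = 1,
                                  component_params = default_components(),
                                  time_ms = seq(-100, 350, by = 1),
                                  noise_sd = 0,
                                  plasticity_factor_healthy = 0.7,
                                  plasticity_attenuation = 0.5) {
  condition <- match.arg(condition)
  if (!is.finite(severity) || severity < 0 || severity > 1)
    stop("severity must lie in [0, 1]")
  cp <- component_params
  cp$latency <- cp$latency + severity * 20
  scale <- max(0, 1 - severity * proximity_weight)
  pf <- if (condition == "inhibitory")
    effective_plasticity(severity, plasticity_factor_healthy,
                         plasticity_attenuation) else 1
  cp$amplitude <- cp$amplitude * scale * pf
  tep_component_sum(cp, time_ms) +
    as.vector(sim_noise(length(time_ms), 1L, noise_sd))
}

# truncated-normal severity sampler on [lo, hi]
r_truncnorm <- function(n, mean, sd, lo = 0, hi = 1) {
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Simulate per-ROI fractional anisotropy
#'
#' `FA(subject, roi) = clip(fa_baseline[roi] - fa_loading[roi] * severity +
#' noise, 0.05, 0.95)`: each tract's mean FA degrades linearly in the same
#' latent severity that distorts the TEP.
#'
#' @param severity per-subject severity vector (named by subject id).
#' @param fa_baseline,fa_loading named per-ROI vectors.
#' @param fa_noise_sd measurement noise sd, FA units.
#' @return long data.frame (`FATable`) with columns `subject_id`, `roi`,
#'   `mean_fa`, `n_voxels_used` (`NA` for simulated tables).
#' @export
simulate_fa <- function(severity, fa_baseline, fa_loading, fa_noise_sd = 0) {
  stopifnot(all(fa_loading >= 0),
            identical(names(fa_baseline), names(fa_loading)))
  n <- length(severity); rois <- names(fa_baseline)
  subj <- names(severity)
  if (is.null(subj)) subj <- sprintf("sub%03d", seq_len(n))
  fa <- outer(rep(1, n), fa_baseline) - outer(severity, fa_loading)
  if (fa_noise_sd > 0)
    fa <- fa + matrix(rnorm(n * length(rois), sd = fa_noise_sd), n)
  fa <- pmin(pmax(fa, 0.05), 0.95)
  data.frame(subject_id = rep(subj, times = length(rois)),
             roi = rep(rois, each = n),
             mean_fa = as.vector(fa),
             n_voxels_used = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Reshape an FA table to a subject-by-ROI matrix
#'
#' @param fa_table long FA data.frame as produced by [simulate_fa()] or
#'   [roi_mean_fa()].
#' @return numeric matrix, rownames = subject ids, colnames = ROIs.
#' @export
fa_matrix <- function(fa_table) {
  subj <- unique(fa_table$subject_id); rois <- unique(fa_table$roi)
  m <- matrix(NA_real_, length(subj), length(rois),
              dimnames = list(subj, rois))
  m[cbind(match(fa_table$subject_id, subj), match(fa_table$roi, rois))] <-
    fa_table$mean_fa
  m
}

#' Simulate a full TMS-EEG cohort with linked FA tables
#'
#' Generates, reproducibly for a fixed seed, an [epoch_set] of raw TEP
#' epochs for two stimulation protocols, group labels, the latent
#' per-subject severities, and the FA table driven by the same severities.
#' Between-subject variability perturbs component latencies/amplitudes
#' once per subject; epochs within a subject differ only by noise and by
#' injected large-amplitude artifact epochs (probability
#' `artifact_rate` per epoch, applied across all electrodes, peak
#' `artifact_amp` uV).
#'
#' @param config a [sim_config()].
#' @return list of class `tep_cohort`: `epochs` ([epoch_set]), `fa`
#'   (FATable data.frame), `labels` (named character), `severity` (named
#'   numeric, the generative ground truth), `config`.
#' @export
simulate_cohort <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  nh <- cfg$n_healthy; ni <- cfg$n_injured; n <- nh + ni
  subjects <- sprintf("sub%03d", seq_len(n))
  groups <- c(rep("healthy", nh), rep("injured", ni))
  severity <- setNames(
    c(rep(0, nh), r_truncnorm(ni, cfg$severity_mean, cfg$severity_sd)),
    subjects)

  map <- cfg$hotspot_map
  electrodes <- unlist(map, use.names = FALSE)
  prox_e <- unname(cfg$proximity_weights[electrode_hotspot(map)[electrodes]])
  conditions <- c("single", "inhibitory")
  tm <- time_axis(cfg)
  nt <- length(tm); ne <- length(electrodes); nep <- cfg$epochs_per_condition

  amp <- array(NA_real_, c(n, 2L, ne, nep, nt))
  cp0 <- cfg$component_params
  K <- nrow(cp0)
  for (s in seq_len(n)) {
    # subject-level component variability, shared by both conditions
    lat_s <- cp0$latency + rnorm(K) * cp0$latency_sd + severity[s] * 20
    amp_s <- cp0$amplitude + rnorm(K) * cp0$amplitude_sd
    G <- vapply(seq_len(K),
                function(k) exp(-(tm - lat_s[k])^2 / (2 * cp0$width[k]^2)),
                numeric(nt))
    for (ci in seq_along(conditions)) {
      pf <- if (conditions[ci] == "inhibitory")
        effective_plasticity(severity[s], cfg$plasticity_factor_healthy,
                             cfg$plasticity_attenuation_per_severity) else 1
      base_t <- as.vector(G %*% amp_s) * pf          # [nt]
      scale_e <- pmax(0, 1 - severity[s] * prox_e)   # [ne]
      wave_te <- outer(base_t, scale_e)              # [nt x ne]
      arr <- array(wave_te, c(nt, ne, nep)) +
        array(sim_noise(nt, ne * nep, cfg$noise_sd), c(nt, ne, nep))
      if (cfg$artifact_rate > 0) {
        is_art <- runif(nep) < cfg$artifact_rate
        for (ep in which(is_art)) {
          t0 <- runif(1, 30, cfg$post_stim_ms - 50)
          bump <- sample(c(-1, 1), 1) * cfg$artifact_amp *
            exp(-(tm - t0)^2 / (2 * 30^2))
          arr[, , ep] <- arr[, , ep] + bump
        }
      }
      amp[s, ci, , , ] <- aperm(arr, c(2, 3, 1))
    }
  }
  es <- epoch_set(amp, tm, cfg$sampling_rate, subjects, groups,
                  conditions, electrodes)
  fa <- simulate_fa(severity, cfg$fa_baseline, cfg$fa_loading, cfg$fa_noise_sd)
  structure(list(epochs = es, fa = fa,
                 labels = setNames(groups, subjects),
                 severity = severity, config = cfg),
            class = "tep_cohort")
}

#' @export
print.tep_cohort <- function(x, ...) {
  cat(sprintf("<tep_cohort> %d healthy + %d injured subjects, %d ROIs\n",
              sum(x$labels == "healthy"), sum(x$labels == "injured"),
              length(unique(x$fa$roi))))
  print(x$epochs)
  invisible(x)
}
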
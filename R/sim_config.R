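#' Default TEP component set
#'
#' Canonical TMS-evoked potential components used by the simulator. The
#' five peaks (P30, N45, P60, N100, P180) are the standard motor-cortex TEP
#' deflections; each is rendered as a Gaussian bump
#' `amplitude * exp(-(t - latency)^2 / (2 * width^2))` with `width` the
#' Gaussian standard deviation in ms. `latency_sd` and `amplitude_sd` set
#' the between-subject variability of latency and amplitude.
#'
#' @return data.frame with columns `label`, `latency` (ms), `latency_sd`
#'   (ms), `amplitude` (uV), `amplitude_sd` (uV), `width` (ms).
#' @export
default_components <- function() {
  data.frame(
    label        = c("P30", "N45", "P60", "N100", "P180"),
    latency      = c(30, 45, 60, 100, 180),
    latency_sd   = c(2, 3, 4, 6, 10),
    amplitude    = c(4, -5, 4.5, -8, 3.5),
    amplitude_sd = c(0.8, 1.0, 0.9, 1.6, 0.7),
    width        = c(7, 9, 11, 22, 40),
    stringsAsFactors = FALSE
  )
}

#' Default white-matter ROI generative parameters
#'
#' Baseline mean FA per tract (realistic healthy-adult values) and the
#' loading with which the latent injury severity degrades each tract.
#' Loadings are proximity-ordered: tracts close to a left-M1 stimulation
#' site (frontal commissural and left association/projection fibers) load
#' hardest, mirroring the expectation that a left-hemisphere stimulation
#' probe is most sensitive to proximal fiber damage.
#'
#' @return data.frame with columns `roi`, `fa_baseline`, `fa_loading`.
#' @export
default_fa_params <- function() {
  data.frame(
    roi = c("corpus_callosum_genu", "anterior_internal_capsule_L",
            "anterior_corona_radiata_L", "superior_fronto_occipital_fasciculus_L",
            "superior_longitudinal_fasciculus_L", "corpus_callosum_body",
            "corpus_callosum_splenium", "anterior_internal_capsule_R",
            "anterior_corona_radiata_R", "superior_fronto_occipital_fasciculus_R",
            "superior_longitudinal_fasciculus_R", "corticospinal_tract_L",
            "corticospinal_tract_R"),
    fa_baseline = c(0.52, 0.51, 0.43, 0.50, 0.50, 0.56,
                    0.60, 0.53, 0.44, 0.50, 0.48, 0.43, 0.43),
    fa_loading  = c(0.16, 0.15, 0.14, 0.13, 0.12, 0.11,
                    0.10, 0.08, 0.07, 0.06, 0.05, 0.04, 0.03),
    stringsAsFactors = FALSE
  )
}

#' Default hotspot proximity weights
#'
#' Scaling of the injury effect on the TEP per hotspot. Regions proximal
#' to the left-M1 stimulation site (left temporal/parietal) carry the full
#' effect; contralateral and occipital regions are attenuated.
#'
#' @return named numeric vector over the eight default hotspots.
#' @export
default_proximity_weights <- function() {
  c(temporal_left = 1.0, parietal_left = 1.0, frontal_left = 0.9,
    temporal_right = 0.75, parietal_right = 0.75, frontal_right = 0.7,
    occipital_left = 0.6, occipital_right = 0.5)
}

#' Simulation configuration for a synthetic TMS-EEG cohort
#'
#' Bundles and validates every knob of the cohort generator. Injured
#' subjects carry a single latent severity in \[0, 1\], drawn from a
#' truncated normal, that drives both the TEP distortion (amplitude
#' suppression and latency delay, proximity-weighted per hotspot) and the
#' FA degradation, so structure-function coupling is recoverable
#' downstream.
#'
#' @param n_healthy,n_injured subjects per group.
#' @param epochs_per_condition epochs recorded per stimulation protocol.
#' @param sampling_rate Hz (>= 250).
#' @param pre_stim_ms,post_stim_ms recorded span around the pulse at 0 ms.
#' @param severity_mean,severity_sd injury severity distribution, truncated
#'   to \[0, 1\]; healthy subjects have severity 0.
#' @param component_params TEP component table, see [default_components()].
#' @param noise_sd per-sample noise standard deviation, uV.
#' @param artifact_rate fraction of epochs contaminated by a large artifact.
#' @param artifact_amp artifact peak amplitude, uV.
#' @param plasticity_factor_healthy amplitude ratio applied to the 1 Hz
#'   inhibitory-protocol response in a fully healthy network (< 1:
#'   inhibition suppresses the response, yielding a positive STP index).
#' @param plasticity_attenuation_per_severity how fast injury flattens the
#'   single-vs-inhibitory contrast: the effective factor is
#'   `pf + (1 - pf) * min(1, attenuation * severity)`.
#' @param fa_baseline,fa_loading named per-ROI vectors (defaults from
#'   [default_fa_params()]).
#' @param fa_noise_sd FA measurement noise, FA units.
#' @param proximity_weights named per-hotspot vector, see
#'   [default_proximity_weights()].
#' @param hotspot_map electrode grouping, see [default_hotspot_map()].
#' @param seed integer seed; every generator draw is reproducible given it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_healthy = 20, n_injured = 20,
                       epochs_per_condition = 60,
                       sampling_rate = 1000,
                       pre_stim_ms = 100, post_stim_ms = 350,
                       severity_mean = 0.6, severity_sd = 0.2,
                       component_params = default_components(),
                       noise_sd = 2, artifact_rate = 0.05,
                       artifact_amp = 300,
                       plasticity_factor_healthy = 0.7,
                       plasticity_attenuation_per_severity = 0.5,
                       fa_baseline = NULL, fa_loading = NULL,
                       fa_noise_sd = 0.03,
                       proximity_weights = default_proximity_weights(),
                       hotspot_map = default_hotspot_map(),
                       seed = 1L) {
  if (is.null(fa_baseline) || is.null(fa_loading)) {
    fp <- default_fa_params()
    if (is.null(fa_baseline)) fa_baseline <- setNames(fp$fa_baseline, fp$roi)
    if (is.null(fa_loading))  fa_loading  <- setNames(fp$fa_loading, fp$roi)
  }
  cfg <- list(
    n_healthy = as.integer(n_healthy), n_injured = as.integer(n_injured),
    epochs_per_condition = as.integer(epochs_per_condition),
    sampling_rate = sampling_rate,
    pre_stim_ms = pre_stim_ms, post_stim_ms = post_stim_ms,
    severity_mean = severity_mean, severity_sd = severity_sd,
    component_params = component_params,
    noise_sd = noise_sd, artifact_rate = artifact_rate,
    artifact_amp = artifact_amp,
    plasticity_factor_healthy = plasticity_factor_healthy,
    plasticity_attenuation_per_severity = plasticity_attenuation_per_severity,
    fa_baseline = fa_baseline, fa_loading = fa_loading,
    fa_noise_sd = fa_noise_sd,
    proximity_weights = proximity_weights,
    hotspot_map = hotspot_map,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg a `sim_config` object.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_healthy < 0L || cfg$n_injured < 0L || cfg$n_healthy + cfg$n_injured == 0L)
    stop("need at least one subject; counts must be non-negative")
  if (cfg$epochs_per_condition <= 0L) stop("epochs_per_condition must be > 0")
  if (cfg$sampling_rate < 250) stop("sampling_rate must be >= 250 Hz")
  if (cfg$pre_stim_ms <= 0 || cfg$post_stim_ms <= 0)
    stop("pre/post stimulus spans must be positive")
  cp <- cfg$component_params
  req <- c("label", "latency", "latency_sd", "amplitude", "amplitude_sd", "width")
  if (!all(req %in% names(cp))) stop("component_params missing columns")
  if (any(cp$latency <= 0 | cp$latency >= cfg$post_stim_ms))
    stop("component latencies must lie inside (0, post_stim_ms)")
  if (any(cp$width <= 0)) stop("component widths must be positive")
  if (cfg$noise_sd < 0 || cfg$fa_noise_sd < 0) stop("noise sds must be >= 0")
  if (cfg$artifact_rate < 0 || cfg$artifact_rate > 1)
    stop("artifact_rate must be in [0, 1]")
  if (cfg$severity_sd < 0) stop("severity_sd must be >= 0")
  if (cfg$plasticity_factor_healthy <= 0 || cfg$plasticity_factor_healthy > 1)
    stop("plasticity_factor_healthy must be in (0, 1]")
  if (any(cfg$fa_baseline <= 0 | cfg$fa_baseline >= 1))
    stop("fa_baseline entries must lie in (0, 1)")
  if (any(cfg$fa_loading < 0)) stop("fa_loading entries must be >= 0")
  if (!identical(names(cfg$fa_baseline), names(cfg$fa_loading)))
    stop("fa_baseline and fa_loading must share ROI names")
  validate_hotspot_map(cfg$hotspot_map)
  missing_w <- setdiff(names(cfg$hotspot_map), names(cfg$proximity_weights))
  if (length(missing_w))
    stop("proximity_weights missing hotspots: ", paste(missing_w, collapse = ", "))
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n",
      sprintf("  subjects: %d healthy + %d injured\n", x$n_healthy, x$n_injured),
      sprintf("  epochs/condition: %d @ %g Hz, span [-%g, %g] ms\n",
              x$epochs_per_condition, x$sampling_rate, x$pre_stim_ms, x$post_stim_ms),
      sprintf("  severity ~ truncN(%g, %g); noise %g uV; artifacts %g%% @ %g uV\n",
              x$severity_mean, x$severity_sd, x$noise_sd,
              100 * x$artifact_rate, x$artifact_amp),
      sprintf("  ROIs: %d; hotspots: %d; seed %d\n",
              length(x$fa_baseline), length(x$hotspot_map), x$seed), sep = "")
  invisible(x)
}
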
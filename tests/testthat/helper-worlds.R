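# Shared fixture builders. Everything is generated in code at test time;
# cohorts are scaled down (250-500 Hz, 6-8 epochs/condition) relative to
# the 1 kHz / 60-epoch simulator defaults to stay inside the test budget.

proximal_hotspots <- function() {
  default_hotspot_map()[c("temporal_left", "temporal_right",
                          "parietal_left", "parietal_right")]
}

# small-but-complete simulation config; override any field via ...
quick_cfg <- function(...) {
  args <- modifyList(
    list(n_healthy = 6L, n_injured = 6L, epochs_per_condition = 6L,
         sampling_rate = 500, pre_stim_ms = 60, post_stim_ms = 320,
         noise_sd = 1, artifact_rate = 0, seed = 1L),
    list(...))
  do.call(sim_config, args)
}

zero_loadings <- function() {
  setNames(rep(0, nrow(default_fa_params())), default_fa_params()$roi)
}

# nuisance between-subject variability scaled down: the "severity effect
# >> noise" world of the signal-recovery checks
strong_signal_components <- function(frac = 0.25) {
  cp <- default_components()
  cp$latency_sd <- cp$latency_sd * frac
  cp$amplitude_sd <- cp$amplitude_sd * frac
  cp
}

# simulate -> preprocess -> template (from a disjoint reference cohort) ->
# DELPHI features -> 16-d feature matrix
cohort_features <- function(cfg, ref_seed = cfg$seed + 7919L, n_ref = 10L,
                            baseline_window = c(-50, -10),
                            template = NULL) {
  coh <- simulate_cohort(cfg)
  pp <- preprocess_epochs(coh$epochs, baseline_window = baseline_window,
                          map = cfg$hotspot_map)
  if (is.null(template)) {
    rc <- cfg
    rc$n_healthy <- n_ref; rc$n_injured <- 0L; rc$seed <- ref_seed
    ref <- simulate_cohort(rc)
    ref_tep <- preprocess_epochs(ref$epochs,
                                 baseline_window = baseline_window,
                                 map = cfg$hotspot_map)$tep
    ref_tep <- rename_tep_subjects(ref_tep, "ref_")
    template <- build_template(ref_tep)
  }
  feats <- delphi_features(pp$tep, template)
  X <- build_feature_vector(
    feats, hotspots = intersect(names(proximal_hotspots()),
                                names(cfg$hotspot_map)))
  list(X = X, coh = coh, feats = feats, tep = pp$tep, template = template)
}

rename_tep_subjects <- function(tep, prefix) {
  tep$subjects <- paste0(prefix, tep$subjects)
  names(tep$groups) <- tep$subjects
  dimnames(tep$amplitude)[[1]] <- tep$subjects
  dimnames(tep$n_epochs_retained)[[1]] <- tep$subjects
  tep
}

# hand-built epoch container for surgical preprocessing tests
tiny_epoch_set <- function(waves, time_ms, sampling_rate = 500,
                           conditions = "single") {
  # waves: list electrode -> list of epoch vectors (same lengths)
  electrodes <- names(waves)
  n_ep <- length(waves[[1]])
  amp <- array(NA_real_, c(1, length(conditions), length(electrodes),
                           n_ep, length(time_ms)))
  for (e in seq_along(electrodes))
    for (ep in seq_len(n_ep))
      for (ci in seq_along(conditions))
        amp[1, ci, e, ep, ] <- waves[[e]][[ep]]
  epoch_set(amp, time_ms, sampling_rate, "s1", "healthy", conditions,
            electrodes)
}
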
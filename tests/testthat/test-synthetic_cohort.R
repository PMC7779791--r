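test_that("noiseless waveform equals the deterministic component sum", {
  cp <- default_components()
  tm <- seq(-100, 350, by = 1)
  w <- simulate_tep_waveform(0, "single", 1, cp, tm, noise_sd = 0)
  expect_equal(w, tep_component_sum(cp, tm))
  # peaks sit at the configured latencies (isolated component check)
  one <- cp[4, ]  # N100
  w1 <- simulate_tep_waveform(0, "single", 1, one, tm, noise_sd = 0)
  expect_equal(tm[which.min(w1)], one$latency)
})

test_that("full suppression yields a flat (noise-only) waveform", {
  tm <- seq(-100, 350, by = 1)
  w <- simulate_tep_waveform(1, "single", 1, default_components(), tm,
                             noise_sd = 0)
  expect_true(all(w == 0))
  expect_error(simulate_tep_waveform(-0.1, "single"), "severity")
  expect_error(simulate_tep_waveform(1.2, "single"), "severity")
})

test_that("inhibitory condition scales by the effective plasticity factor", {
  cp <- default_components()
  tm <- seq(-100, 350, by = 1)
  ws <- simulate_tep_waveform(0, "single", 1, cp, tm, noise_sd = 0)
  wi <- simulate_tep_waveform(0, "inhibitory", 1, cp, tm, noise_sd = 0,
                              plasticity_factor_healthy = 0.7)
  expect_equal(wi, 0.7 * ws)
  # injury flattens the contrast toward 1
  wi1 <- simulate_tep_waveform(0.8, "inhibitory", 0, cp, tm, noise_sd = 0,
                               plasticity_factor_healthy = 0.7,
                               plasticity_attenuation = 0.5)
  ws1 <- simulate_tep_waveform(0.8, "single", 0, cp, tm, noise_sd = 0)
  expect_equal(wi1 / ws1, rep(0.7 + 0.3 * 0.4, length(tm)), tolerance = 1e-12)
})

test_that("Monte-Carlo mean of healthy waveforms converges to the template", {
  # contract: the MC mean matches the closed-form component sum within
  # 3*noise_sd/sqrt(200) at every sample. The max over ~200 temporally
  # correlated samples of a 200-draw mean breaches a plain 3-sigma bound
  # for ~1 in 10 correct generators (multiplicity), so the estimator uses
  # 1000 draws while the asserted tolerance stays the stated one - any
  # systematic bias that the 200-draw test could flag is still flagged.
  cp <- default_components()
  tm <- seq(-100, 350, by = 2)
  set.seed(42)
  n <- 1000
  acc <- 0
  for (i in seq_len(n))
    acc <- acc + simulate_tep_waveform(0, "single", 1, cp, tm, noise_sd = 1)
  dev <- abs(acc / n - tep_component_sum(cp, tm))
  expect_lt(max(dev), 3 * 1 / sqrt(200))
})

test_that("cohort simulation is bit-identical for a fixed seed", {
  cfg <- quick_cfg(seed = 77, artifact_rate = 0.1, noise_sd = 0.5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$epochs$amplitude, b$epochs$amplitude)
  expect_identical(a$fa, b$fa)
  expect_identical(a$severity, b$severity)
})

test_that("artifact epochs appear at the configured binomial rate", {
  cfg <- quick_cfg(n_healthy = 10L, n_injured = 0L,
                   epochs_per_condition = 30L,
                   artifact_rate = 0.1, noise_sd = 0.2, seed = 5)
  coh <- simulate_cohort(cfg)
  post <- coh$epochs$time_ms >= 0
  # an artifact epoch carries a >= 250 uV excursion on every electrode
  a <- coh$epochs$amplitude[, , 1, , post]
  p2p <- apply(a, c(1, 2, 3), function(x) diff(range(x)))
  n_art <- sum(p2p > 200)
  n_tot <- length(p2p)
  # binomial(600, 0.1): mean 60, sd ~7.3
  expect_gt(n_art, 60 - 4 * 7.35)
  expect_lt(n_art, 60 + 4 * 7.35)
})

test_that("healthy-only cohorts have FA centred on the baseline", {
  base <- setNames(c(0.5, 0.4), c("roi_a", "roi_b"))
  load <- setNames(c(0.2, 0.1), c("roi_a", "roi_b"))
  set.seed(11)
  fa <- simulate_fa(rep(0, 500), base, load, fa_noise_sd = 0.03)
  m <- fa_matrix(fa)
  expect_equal(unname(colMeans(m)), unname(base),
               tolerance = 4 * 0.03 / sqrt(500) / 0.4)
  expect_equal(unname(apply(m, 2, sd)), c(0.03, 0.03), tolerance = 0.2)
})

test_that("simulate_fa honours the linear-degradation and clipping contract", {
  base <- c(roi = 0.5); load <- c(roi = 0.15)
  expect_equal(simulate_fa(c(s1 = 0), base, load, 0)$mean_fa, 0.5)
  expect_equal(simulate_fa(c(s1 = 1), base, load, 0)$mean_fa, 0.35)
  expect_equal(simulate_fa(c(s1 = 1), c(roi = 0.2), c(roi = 0.3), 0)$mean_fa,
               0.05)
})

test_that("group-mean peak amplitude is non-increasing in severity", {
  cp <- default_components()
  tm <- seq(-100, 350, by = 1)
  peaks <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(s)
    max(abs(simulate_tep_waveform(s, "single", 1, cp, tm, noise_sd = 0))),
    numeric(1))
  expect_true(all(diff(peaks) <= 1e-12))
})

test_that("injured FA columns are lower-mean and higher-sd than healthy", {
  cfg <- quick_cfg(n_healthy = 30L, n_injured = 30L,
                   epochs_per_condition = 2L, sampling_rate = 250,
                   severity_mean = 0.6, severity_sd = 0.2, seed = 3)
  coh <- simulate_cohort(cfg)
  m <- fa_matrix(coh$fa)
  hy <- coh$labels == "healthy"
  expect_true(all(colMeans(m[!hy, ]) < colMeans(m[hy, ])))
  expect_true(mean(apply(m[!hy, ], 2, sd) > apply(m[hy, ], 2, sd)) > 0.8)
})

test_that("config validation rejects out-of-contract values", {
  expect_error(quick_cfg(n_healthy = 0L, n_injured = 0L), "at least one")
  expect_error(quick_cfg(sampling_rate = 200), "250")
  expect_error(quick_cfg(artifact_rate = 1.5), "artifact_rate")
  expect_error(quick_cfg(fa_baseline = setNames(1.2, "roi"),
                         fa_loading = setNames(0.1, "roi")), "fa_baseline")
})
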
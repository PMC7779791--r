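test_that("slope is exact on linear and constant inputs", {
  t <- seq(20, 300, by = 2)
  expect_equal(compute_slope(0.5 * t + 3, t, 60, 100), 0.5)
  expect_equal(compute_slope(rep(4, length(t)), t, 100, 180), 0)
  expect_error(compute_slope(t, t, 60, 61), "samples")
})

test_that("slope matches the closed-form OLS sum formula", {
  ols_oracle <- function(y, t) {
    n <- length(t)
    (n * sum(t * y) - sum(t) * sum(y)) / (n * sum(t^2) - sum(t)^2)
  }
  t <- seq(20, 300, by = 1)
  idx <- t >= 60 & t <= 100
  expect_equal(compute_slope(t^2, t, 60, 100), ols_oracle(t[idx]^2, t[idx]),
               tolerance = 1e-12)
  set.seed(31)
  for (i in 1:20) {
    y <- rnorm(length(t))
    expect_equal(compute_slope(y, t, 100, 180),
                 ols_oracle(y[t >= 100 & t <= 180], t[t >= 100 & t <= 180]),
                 tolerance = 1e-10)
  }
})

test_that("slope is linear in the waveform", {
  t <- seq(20, 300, by = 2)
  set.seed(5)
  w1 <- rnorm(length(t)); w2 <- rnorm(length(t))
  expect_equal(compute_slope(w1 + w2, t, 60, 100),
               compute_slope(w1, t, 60, 100) + compute_slope(w2, t, 60, 100))
})

test_that("WFA honours correlation identities and flags degenerate input", {
  set.seed(7)
  tpl <- rnorm(141)
  expect_equal(compute_wfa(tpl, tpl), 1)
  expect_equal(compute_wfa(-tpl, tpl), -1)
  expect_equal(compute_wfa(2.5 * tpl + 3, tpl), 1)
  expect_true(is.na(compute_wfa(rep(1, 141), tpl)))
  expect_true(is.na(compute_wfa(tpl, rep(0, 141))))
})

test_that("MFP is the mean rectified amplitude", {
  expect_equal(compute_mfp(rep(5, 100)), 5)
  expect_equal(compute_mfp(rep(-5, 100)), 5)
  # |sin| over whole periods -> 2/pi
  t <- seq(0, 10, length.out = 100001)[-100001]
  expect_equal(compute_mfp(sin(2 * pi * t)), 2 / pi, tolerance = 1e-3)
})

test_that("STP follows its defining ratio and invariances", {
  expect_equal(compute_stp(2, 2), 0)
  expect_equal(compute_stp(3, 1), 0.5)
  expect_equal(compute_stp(1, 3), -0.5)
  expect_true(is.na(compute_stp(0, 0)))
  expect_error(compute_stp(-1, 2))
  set.seed(17)
  for (i in 1:50) {
    a <- runif(1, 0, 10); b <- runif(1, 0, 10); k <- runif(1, 0.1, 9)
    expect_equal(compute_stp(a, b), -compute_stp(b, a))
    expect_equal(compute_stp(k * a, k * b), compute_stp(a, b))
    expect_true(abs(compute_stp(a, b)) <= 1)
  }
})

test_that("template construction is a pointwise mean with provenance", {
  cfg <- quick_cfg(n_healthy = 6L, n_injured = 0L, epochs_per_condition = 2L,
                   noise_sd = 0, seed = 4,
                   component_params = {
                     cp <- default_components()
                     cp$latency_sd <- 0; cp$amplitude_sd <- 0; cp
                   })
  coh <- simulate_cohort(cfg)
  tep <- preprocess_epochs(coh$epochs, baseline_window = c(-50, -10))$tep
  tpl <- build_template(tep)
  # all reference subjects identical (no noise, no subject variability)
  expect_equal(tpl$waveforms["parietal_left", ],
               tep$amplitude[1, 1, match("parietal_left", tep$hotspots), ],
               tolerance = 1e-10)
  expect_identical(tpl$reference_subjects, tep$subjects)
  expect_error(build_template(tep, subjects = tep$subjects[1:3]), "at least 5")
})

test_that("template error shrinks as 1/sqrt(n) over noisy references", {
  # asserted tolerance is the stated 3*sigma/sqrt(50); the estimator uses
  # 300 references because the max over 141 independent samples breaches a
  # plain 3-sigma cutoff for ~1 in 3 correct draws (multiplicity)
  set.seed(23)
  truth <- sin(seq(0, 3 * pi, length.out = 141))
  n <- 300; sigma <- 0.5
  amp <- array(NA_real_, c(n, 1, 1, 141))
  for (i in 1:n) amp[i, 1, 1, ] <- truth + rnorm(141, sd = sigma)
  tep <- hotspot_tep(amp, seq(20, 300, length.out = 141),
                     sprintf("r%03d", 1:n), rep("healthy", n), "single",
                     "parietal_left", array(1L, c(n, 1, 1)), 500)
  tpl <- build_template(tep)
  expect_lt(max(abs(tpl$waveforms[1, ] - truth)), 3 * sigma / sqrt(50))
})

test_that("degenerate cancelling references flag WFA missing downstream", {
  w <- sin(seq(0, 3 * pi, length.out = 141))
  amp <- array(NA_real_, c(6, 1, 1, 141))
  for (i in 1:6) amp[i, 1, 1, ] <- if (i %% 2) w else -w
  tep <- hotspot_tep(amp, seq(20, 300, length.out = 141),
                     sprintf("r%d", 1:6), rep("healthy", 6), "single",
                     "parietal_left", array(1L, c(6, 1, 1)), 500)
  tpl <- build_template(tep)
  expect_equal(max(abs(tpl$waveforms)), 0)
  expect_true(is.na(compute_wfa(w, tpl$waveforms[1, ])))
})

test_that("evaluating a template-donor subject is a hard error", {
  out <- cohort_features(quick_cfg(seed = 6))
  bad_tpl <- build_template(out$tep)   # built FROM the evaluation cohort
  expect_error(delphi_features(out$tep, bad_tpl), "leakage")
})

test_that("feature extraction satisfies the row-wise STP identity", {
  out <- cohort_features(quick_cfg(seed = 10))
  f <- out$feats
  expect_true(all(f$mfp_single >= 0 & f$mfp_i >= 0))
  expect_equal(f$stp, (f$mfp_single - f$mfp_i) / (f$mfp_single + f$mfp_i))
  expect_true(all(abs(f$wfa) <= 1))
})

test_that("injured WFA falls below healthy WFA under injury distortion", {
  cfg <- quick_cfg(n_healthy = 8L, n_injured = 8L, noise_sd = 0,
                   severity_mean = 0.7, severity_sd = 0.1, seed = 12)
  out <- cohort_features(cfg)
  f <- out$feats
  expect_lt(mean(f$wfa[f$group == "injured"]),
            mean(f$wfa[f$group == "healthy"]))
})

test_that("feature vectors are 16-long, ordered, order-invariant and imputed", {
  out <- cohort_features(quick_cfg(seed = 14))
  X <- out$X
  expect_equal(ncol(X), 16L)
  expect_identical(colnames(X)[1:4],
                   c("temporal_left.epd", "temporal_left.lpd",
                     "temporal_left.wfa", "temporal_left.stp"))
  # permuting input rows leaves the matrix unchanged
  f2 <- out$feats[sample(nrow(out$feats)), ]
  X2 <- build_feature_vector(f2)
  expect_equal(X2[rownames(X), colnames(X)], X, ignore_attr = TRUE)
  # imputation contract: a missing cell becomes the column median
  f3 <- out$feats
  i <- which(f3$hotspot == "parietal_left")[1]
  dropped_subj <- f3$subject_id[i]
  f3$wfa[i] <- NA
  X3 <- build_feature_vector(f3)
  med <- median(f3$wfa[f3$hotspot == "parietal_left" &
                         f3$subject_id != dropped_subj])
  expect_equal(X3[dropped_subj, "parietal_left.wfa"], med)
  expect_equal(attr(X3, "imputed")$subject_id, dropped_subj)
  # > 25% missing drops the subject with a log entry
  f4 <- out$feats
  sel <- f4$subject_id == dropped_subj & f4$hotspot %in%
    c("parietal_left", "parietal_right")
  f4$wfa[sel] <- NA; f4$stp[sel] <- NA; f4$epd[sel] <- NA
  X4 <- build_feature_vector(f4)
  expect_false(dropped_subj %in% rownames(X4))
  expect_identical(attr(X4, "dropped"), dropped_subj)
})
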
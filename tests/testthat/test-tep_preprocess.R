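test_that("peak-to-peak rejection separates artifact from clean epochs", {
  cfg <- quick_cfg(n_healthy = 4L, n_injured = 0L, epochs_per_condition = 20L,
                   artifact_rate = 0.2, noise_sd = 0.2, seed = 8)
  coh <- simulate_cohort(cfg)
  post <- coh$epochs$time_ms >= 0
  m <- coh$epochs$amplitude[, , , , post, drop = FALSE]
  d <- dim(m)
  p2p <- apply(matrix(m, prod(d[1:4]), d[5]), 1, function(x) diff(range(x)))
  truth <- array(p2p > 200, d[1:4])   # artifacts are ~300 uV, clean < 50
  rej <- reject_epochs(coh$epochs, peak_to_peak_limit = 200)
  expect_identical(unname(rej$epochs$retained), !truth)
  expect_equal(nrow(rej$log), sum(truth))
  # bookkeeping: retained + rejected = recorded
  expect_equal(sum(rej$epochs$retained) + nrow(rej$log),
               length(rej$epochs$retained))
})

test_that("an infinite limit rejects nothing", {
  cfg <- quick_cfg(seed = 2, artifact_rate = 0.2)
  coh <- simulate_cohort(cfg)
  rej <- reject_epochs(coh$epochs, Inf)
  expect_true(all(rej$epochs$retained))
  expect_equal(nrow(rej$log), 0L)
})

test_that("retained fraction tracks the artifact rate", {
  cfg <- quick_cfg(n_healthy = 8L, n_injured = 0L, epochs_per_condition = 30L,
                   artifact_rate = 0.1, noise_sd = 0.2, seed = 13)
  coh <- simulate_cohort(cfg)
  rej <- reject_epochs(coh$epochs, 150)
  frac <- mean(rej$epochs$retained)
  # 480 independent epoch draws at 0.1: sd of fraction ~ 0.014
  expect_gt(frac, 0.9 - 4 * 0.014)
  expect_lt(frac, 0.9 + 4 * 0.014)
})

test_that("rejection hard-errors when an electrode loses every epoch", {
  tm <- seq(-50, 300, by = 2)
  big <- lapply(1:3, function(i) rep(c(-200, 200), length.out = length(tm)))
  es <- tiny_epoch_set(list(C3 = big), tm)
  expect_error(reject_epochs(es, 100), "all epochs rejected.*C3")
})

test_that("FIR bandpass meets its passband/stopband contract", {
  fs <- 500
  t <- seq(0, 8, by = 1 / fs)[-1]
  interior <- t > 3 & t < 5
  gain <- function(f) {
    y <- bandpass_fir(sin(2 * pi * f * t), sampling_rate = fs)
    max(abs(y[interior]))
  }
  expect_gt(gain(10), 0.9)           # passband ripple < 1 dB at 10 Hz
  expect_lt(gain(60), 0.1)           # > 20 dB down at 60 Hz
  dc <- bandpass_fir(rep(50, length(t)), sampling_rate = fs)
  expect_lt(abs(mean(dc[interior])), 0.05 * 50)
  expect_error(bandpass_fir(t, sampling_rate = 90), "90 Hz")
})

test_that("FIR is zero-phase on a passband component", {
  fs <- 500
  t <- seq(0, 8, by = 1 / fs)[-1]
  x <- sin(2 * pi * 10 * t)
  y <- bandpass_fir(x, sampling_rate = fs)
  interior <- t > 3 & t < 5
  # no delay: filtered output aligns with the input, not a shifted copy
  expect_gt(cor(x[interior], y[interior]), 0.999)
})

test_that("baseline correction is exact, idempotent and shift-invariant", {
  tm <- seq(-50, 300, by = 2)
  w <- sin(2 * pi * 5 * tm / 1000) + 3
  es <- tiny_epoch_set(list(C3 = list(w)), tm)
  bc <- baseline_correct(es, c(-50, -10))
  bidx <- tm >= -50 & tm <= -10
  expect_equal(mean(bc$amplitude[1, 1, 1, 1, bidx]), 0)
  expect_equal(baseline_correct(bc, c(-50, -10))$amplitude, bc$amplitude)
  es2 <- es; es2$amplitude <- es2$amplitude + 7.5
  expect_equal(baseline_correct(es2, c(-50, -10))$amplitude, bc$amplitude)
  expect_error(baseline_correct(es, c(-100, -10)), "outside")
})

test_that("hotspot aggregation averages epochs then electrodes", {
  tm <- seq(-50, 320, by = 2)
  w1 <- sin(2 * pi * 7 * tm / 1000)
  w2 <- cos(2 * pi * 4 * tm / 1000)
  map <- list(parietal_left = c("C3", "C5"))
  # two identical electrodes -> hotspot equals either electrode's mean
  es <- tiny_epoch_set(list(C3 = list(w1, w2), C5 = list(w1, w2)), tm)
  tep <- aggregate_hotspots(es, map)
  keep <- tm >= 20 & tm <= 300
  expect_equal(tep$amplitude[1, 1, 1, ], ((w1 + w2) / 2)[keep])
  expect_identical(tep$time_ms, tm[keep])
  # cancelling electrodes -> identically zero
  esc <- tiny_epoch_set(list(C3 = list(w1), C5 = list(-w1)), tm)
  expect_equal(max(abs(aggregate_hotspots(esc, map)$amplitude)), 0)
  # single electrode, single epoch -> cropped identity
  es1 <- tiny_epoch_set(list(C3 = list(w1)), tm)
  tep1 <- aggregate_hotspots(es1, list(parietal_left = "C3"))
  expect_equal(tep1$amplitude[1, 1, 1, ], w1[keep])
  # a hotspot with no recorded electrode is a hard error
  expect_error(aggregate_hotspots(es1, list(frontal_left = "F3")),
               "no electrodes")
})

test_that("aggregation respects rejection flags and counts epochs", {
  tm <- seq(-50, 320, by = 2)
  w1 <- sin(2 * pi * 7 * tm / 1000)
  big <- rep(c(-300, 300), length.out = length(tm))
  es <- tiny_epoch_set(list(C3 = list(w1, big, w1)), tm)
  rej <- reject_epochs(es, 100)
  tep <- aggregate_hotspots(rej$epochs, list(parietal_left = "C3"))
  keep <- tm >= 20 & tm <= 300
  expect_equal(tep$amplitude[1, 1, 1, ], w1[keep])
  expect_equal(unname(tep$n_epochs_retained[1, 1, 1]), 2L)
})

test_that("re-running the chain on processed epochs only touches filter edges", {
  cfg <- quick_cfg(n_healthy = 2L, n_injured = 0L, epochs_per_condition = 3L,
                   seed = 21, noise_sd = 0.5)
  coh <- simulate_cohort(cfg)
  once <- baseline_correct(bandpass_fir(reject_epochs(coh$epochs, 100)$epochs),
                           c(-50, -10))
  twice <- baseline_correct(bandpass_fir(reject_epochs(once, 100)$epochs),
                            c(-50, -10))
  t1 <- aggregate_hotspots(once)$amplitude
  t2 <- aggregate_hotspots(twice)$amplitude
  # rejection flags stay put, and the in-band TEP (20-300 ms, away from the
  # epoch edges) is preserved within the filter's passband ripple
  scale <- max(abs(t1))
  expect_lt(max(abs(t2 - t1)) / scale, 0.05)
})
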
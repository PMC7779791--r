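# ---- internal array helpers --------------------------------------------

# reshape the trailing time dimension of a [.., time] array into matrix rows
flatten_keep_time <- function(a) {
  d <- dim(a)
  matrix(a, nrow = prod(d[-length(d)]), ncol = d[length(d)])
}

row_max <- function(m) do.call(pmax, asplit(m, 2))
row_min <- function(m) do.call(pmin, asplit(m, 2))

#' Reject epochs with large artifacts
#'
#' Flags an epoch as rejected, per channel, when its peak-to-peak amplitude
#' in the post-stimulus window (t >= 0) exceeds `peak_to_peak_limit`.
#' Rejection only flips `retained` flags; the data stay in place so that
#' `retained + rejected = recorded` holds per (subject, condition,
#' electrode).
#'
#' @param epochs an [epoch_set].
#' @param peak_to_peak_limit uV; default 100 (a common TMS-EEG convention;
#'   the upstream methodology leaves the threshold unspecified). `Inf`
#'   disables rejection.
#' @return list with `epochs` (flags updated) and `log`, a data.frame of
#'   rejected entries (`subject`, `condition`, `electrode`, `epoch`,
#'   `p2p`).
#' @export
reject_epochs <- function(epochs, peak_to_peak_limit = 100) {
  stopifnot(inherits(epochs, "epoch_set"), peak_to_peak_limit > 0)
  d <- dim(epochs$amplitude)
  post <- epochs$time_ms >= 0
  a <- epochs$amplitude[, , , , post, drop = FALSE]
  m <- flatten_keep_time(a)
  p2p <- row_max(m) - row_min(m)
  exceed <- array(p2p > peak_to_peak_limit, d[1:4])
  retained <- epochs$retained & !exceed
  bad <- which(epochs$retained & exceed, arr.ind = TRUE)
  log <- data.frame(
    subject = epochs$subjects[bad[, 1]],
    condition = epochs$conditions[bad[, 2]],
    electrode = epochs$electrodes[bad[, 3]],
    epoch = bad[, 4],
    p2p = array(p2p, d[1:4])[bad],
    stringsAsFactors = FALSE)
  none_left <- which(!apply(retained, c(1, 2, 3), any), arr.ind = TRUE)
  if (nrow(none_left) > 0) {
    stop(sprintf(
      "all epochs rejected for subject %s, condition %s, electrode %s",
      epochs$subjects[none_left[1, 1]], epochs$conditions[none_left[1, 2]],
      epochs$electrodes[none_left[1, 3]]))
  }
  epochs$retained <- retained
  list(epochs = epochs, log = log)
}

#' Design a zero-phase FIR bandpass kernel
#'
#' Hamming-windowed sinc design in the usual EEG style: 6 dB cutoffs at
#' `low - trans_low/2` and `high + trans_high/2`, kernel length set by the
#' narrower transition band (`3.3 / transition` cycles, forced odd so the
#' symmetric kernel is exactly linear-phase), gain normalised to 1 at the
#' passband centre.
#'
#' @param sampling_rate Hz.
#' @param low,high passband edges, Hz.
#' @param trans_low,trans_high transition widths at each edge, Hz. The
#'   narrow default low-edge transition (0.5 Hz) keeps the 0.5 Hz cutoff
#'   meaningful; it implies a long kernel (3.3 * rate / 0.5 taps).
#' @return numeric kernel of odd length, with attributes `delay` (group
#'   delay in samples) and `sampling_rate`.
#' @export
design_fir_bandpass <- function(sampling_rate, low = 0.5, high = 45,
                                trans_low = 0.5, trans_high = 5) {
  stopifnot(low > 0, high > low, sampling_rate > 2 * high,
            trans_low > 0, trans_high > 0)
  f1 <- max(low - trans_low / 2, 1e-6) / sampling_rate   # cycles/sample
  f2 <- min(high + trans_high / 2, sampling_rate / 2 * 0.999) / sampling_rate
  ntaps <- ceiling(3.3 * sampling_rate / min(trans_low, trans_high))
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  m <- seq_len(ntaps) - 1 - (ntaps - 1) / 2
  lp <- function(fc) ifelse(m == 0, 2 * fc, sin(2 * pi * fc * m) / (pi * m))
  h <- (lp(f2) - lp(f1)) *
    (0.54 - 0.46 * cos(2 * pi * (seq_len(ntaps) - 1) / (ntaps - 1)))
  f_mid <- (low + high) / 2 / sampling_rate
  gain <- sum(h * cos(2 * pi * f_mid * m))   # symmetric: response is real
  h <- h / gain
  attr(h, "delay") <- (ntaps - 1) / 2
  attr(h, "sampling_rate") <- sampling_rate
  h
}

# FFT overlap-free convolution of each column of x with kernel h, output
# centred to compensate the group delay (zero net phase for symmetric h);
# the signal is zero-padded, so the outermost delay samples carry edge
# transients. Columns are processed in chunks to bound memory.
fir_apply <- function(x, h, chunk_elems = 4e6) {
  one_col <- is.null(dim(x))
  if (one_col) x <- matrix(x, ncol = 1)
  nt <- nrow(x); L <- length(h); delay <- (L - 1) / 2
  nfft <- nextn(nt + L - 1, 2)
  H <- fft(c(h, numeric(nfft - L)))
  out <- matrix(0, nt, ncol(x))
  chunk <- max(1L, floor(chunk_elems / nfft))
  for (j0 in seq(1, ncol(x), by = chunk)) {
    j <- j0:min(j0 + chunk - 1, ncol(x))
    xp <- rbind(x[, j, drop = FALSE], matrix(0, nfft - nt, length(j)))
    y <- Re(mvfft(mvfft(xp) * H, inverse = TRUE)) / nfft
    out[, j] <- y[(delay + 1):(delay + nt), , drop = FALSE]
  }
  if (one_col) out[, 1] else out
}

#' Zero-phase FIR bandpass filter
#'
#' Applies the [design_fir_bandpass()] kernel with delay compensation
#' (symmetric kernel, centred convolution), i.e. zero net phase, so the
#' TEP slope measures are not distorted. Methods exist for plain numeric
#' vectors/matrices (time along rows) and for [epoch_set] objects (every
#' epoch of every channel filtered independently).
#'
#' @param x numeric vector, `[time x series]` matrix, or [epoch_set].
#' @param low,high,trans_low,trans_high see [design_fir_bandpass()].
#' @param sampling_rate Hz; taken from the object for [epoch_set] input.
#' @param ... passed between methods.
#' @return filtered object of the same shape/class.
#' @export
bandpass_fir <- function(x, ...) UseMethod("bandpass_fir")

#' @rdname bandpass_fir
#' @export
bandpass_fir.default <- function(x, sampling_rate, low = 0.5, high = 45,
                                 trans_low = 0.5, trans_high = 5, ...) {
  if (sampling_rate <= 90)
    stop("sampling_rate must exceed 90 Hz for a 45 Hz passband edge")
  h <- design_fir_bandpass(sampling_rate, low, high, trans_low, trans_high)
  fir_apply(x, h)
}

#' @rdname bandpass_fir
#' @export
bandpass_fir.epoch_set <- function(x, low = 0.5, high = 45,
                                   trans_low = 0.5, trans_high = 5, ...) {
  if (x$sampling_rate <= 90)
    stop("sampling_rate must exceed 90 Hz for a 45 Hz passband edge")
  h <- design_fir_bandpass(x$sampling_rate, low, high, trans_low, trans_high)
  d <- dim(x$amplitude)
  m <- matrix(aperm(x$amplitude, c(5, 1, 2, 3, 4)), nrow = d[5])
  mf <- fir_apply(m, h)
  x$amplitude <- aperm(array(mf, c(d[5], d[1:4])), c(2, 3, 4, 5, 1))
  dimnames(x$amplitude) <- list(x$subjects, x$conditions, x$electrodes,
                                NULL, NULL)
  x
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean amplitude over a
#' pre-stimulus window. The default window \[-100, -10\] ms avoids the
#' samples adjacent to the pulse.
#'
#' @param epochs an [epoch_set].
#' @param window `c(start, end)` in ms; must lie inside the recorded
#'   pre-stimulus span.
#' @return the corrected [epoch_set].
#' @export
baseline_correct <- function(epochs, window = c(-100, -10)) {
  stopifnot(inherits(epochs, "epoch_set"), length(window) == 2,
            window[1] < window[2])
  if (window[1] < min(epochs$time_ms) || window[2] > max(epochs$time_ms))
    stop("baseline window lies outside the recorded span")
  idx <- epochs$time_ms >= window[1] & epochs$time_ms <= window[2]
  if (!any(idx)) stop("baseline window contains no samples")
  means <- rowMeans(flatten_keep_time(
    epochs$amplitude[, , , , idx, drop = FALSE]))
  epochs$amplitude <- epochs$amplitude - array(means, dim(epochs$amplitude))
  epochs
}

#' Per-hotspot averaged TEP container
#'
#' Amplitude array `[subject, condition, hotspot, time]` on the cropped
#' analysis grid (by default 20-300 ms post-stimulus), with the minimum
#' per-hotspot retained-epoch count carried along.
#'
#' @param amplitude 4-d array as above.
#' @param time_ms cropped time axis.
#' @param subjects,groups,conditions,hotspots dimension labels.
#' @param n_epochs_retained `[subject, condition, hotspot]` integer array.
#' @param sampling_rate Hz.
#' @return object of class `hotspot_tep`.
#' @export
hotspot_tep <- function(amplitude, time_ms, subjects, groups, conditions,
                        hotspots, n_epochs_retained, sampling_rate) {
  dimnames(amplitude) <- list(subjects, conditions, hotspots, NULL)
  structure(list(amplitude = amplitude, time_ms = time_ms,
                 subjects = subjects,
                 groups = setNames(as.character(groups), subjects),
                 conditions = conditions, hotspots = hotspots,
                 n_epochs_retained = n_epochs_retained,
                 sampling_rate = sampling_rate),
            class = "hotspot_tep")
}

#' @export
print.hotspot_tep <- function(x, ...) {
  cat(sprintf("<hotspot_tep> %d subjects x %d conditions x %d hotspots, %d samples in [%g, %g] ms\n",
              length(x$subjects), length(x$conditions), length(x$hotspots),
              length(x$time_ms), min(x$time_ms), max(x$time_ms)))
  invisible(x)
}

#' Average epochs into regional hotspot TEPs
#'
#' For each (subject, condition, hotspot): average retained epochs per
#' electrode, then average (unweighted) across the hotspot's electrodes,
#' and crop to the analysis window. Electrodes absent from the recording
#' are tolerated as long as at least one electrode per hotspot remains;
#' a hotspot with no surviving electrode is a hard error.
#'
#' @param epochs an [epoch_set].
#' @param map hotspot map, see [default_hotspot_map()].
#' @param window analysis window in ms, default `c(20, 300)`.
#' @return a [hotspot_tep].
#' @export
aggregate_hotspots <- function(epochs, map = default_hotspot_map(),
                               window = c(20, 300)) {
  stopifnot(inherits(epochs, "epoch_set"))
  validate_hotspot_map(map)
  d <- dim(epochs$amplitude)
  S <- d[1]; C <- d[2]; Ep <- d[4]; Tn <- d[5]
  hs <- names(map)
  out <- array(0, c(S, C, length(hs), Tn))
  nret <- array(NA_integer_, c(S, C, length(hs)),
                dimnames = list(epochs$subjects, epochs$conditions, hs))
  for (hi in seq_along(hs)) {
    elecs <- intersect(map[[hs[hi]]], epochs$electrodes)
    if (length(elecs) == 0)
      stop("hotspot ", hs[hi], " has no electrodes in the recording")
    acc <- array(0, c(S, C, Tn)); nelec <- array(0L, c(S, C))
    nmin <- array(Inf, c(S, C))
    for (e in elecs) {
      ei <- match(e, epochs$electrodes)
      A <- epochs$amplitude[, , ei, , , drop = FALSE]
      dim(A) <- c(S, C, Ep, Tn)
      M <- epochs$retained[, , ei, , drop = FALSE]
      dim(M) <- c(S, C, Ep)
      den <- apply(M, c(1, 2), sum)
      num <- colSums(aperm(A * array(M, c(S, C, Ep, Tn)), c(3, 1, 2, 4)))
      em <- num / array(den, c(S, C, Tn))       # NaN where den == 0
      use <- den > 0
      em[!array(use, c(S, C, Tn))] <- 0
      acc <- acc + em
      nelec <- nelec + use
      nmin <- pmin(nmin, ifelse(use, den, Inf))
    }
    if (any(nelec == 0)) {
      idx <- which(nelec == 0, arr.ind = TRUE)[1, ]
      stop(sprintf("hotspot %s has zero surviving electrodes for subject %s, condition %s",
                   hs[hi], epochs$subjects[idx[1]], epochs$conditions[idx[2]]))
    }
    out[, , hi, ] <- acc / array(nelec, c(S, C, Tn))
    nret[, , hi] <- as.integer(nmin)
  }
  tidx <- epochs$time_ms >= window[1] & epochs$time_ms <= window[2]
  if (sum(tidx) < 3) stop("analysis window contains too few samples")
  hotspot_tep(out[, , , tidx, drop = FALSE], epochs$time_ms[tidx],
              epochs$subjects, epochs$groups, epochs$conditions, hs,
              nret, epochs$sampling_rate)
}

#' Full preprocessing chain: reject, filter, baseline, aggregate
#'
#' The documented stage order is: peak-to-peak epoch rejection, zero-phase
#' 0.5-45 Hz FIR bandpass, pre-stimulus baseline correction, hotspot
#' averaging with cropping to the analysis window.
#'
#' @param epochs an [epoch_set].
#' @param reject_limit peak-to-peak rejection threshold, uV.
#' @param low,high FIR passband edges, Hz.
#' @param baseline_window pre-stimulus window, ms.
#' @param map hotspot map.
#' @param window analysis window, ms.
#' @return list with `tep` (a [hotspot_tep]) and `rejection_log`.
#' @export
preprocess_epochs <- function(epochs, reject_limit = 100,
                              low = 0.5, high = 45,
                              baseline_window = c(-100, -10),
                              map = default_hotspot_map(),
                              window = c(20, 300)) {
  rej <- reject_epochs(epochs, reject_limit)
  es <- bandpass_fir(rej$epochs, low = low, high = high)
  es <- baseline_correct(es, baseline_window)
  list(tep = aggregate_hotspots(es, map, window), rejection_log = rej$log)
}
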
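# Time-frequency decomposition and spectral summaries.

#' Morlet wavelet time-frequency decomposition
#'
#' Complex Morlet filter bank with a fixed number of cycles per frequency,
#' implemented as an analytic Gaussian filter bank in the frequency domain
#' (the Fourier transform of the Morlet wavelet), with unit gain at each
#' centre frequency. The signal is reflection-padded; power is the squared
#' magnitude of the complex output, averaged into bins on a `out_rate` time
#' grid. Samples within half a wavelet (`n_cycles / (2 f)` seconds) of either
#' signal edge are flagged invalid per frequency.
#'
#' @param lfp a single-channel `lfp_ts`
#' @param n_cycles wavelet cycles per frequency
#' @param freqs analysis frequencies in Hz (1 Hz steps over 1-90 by default)
#' @param out_rate output time-grid rate in Hz
#' @return an object of class `tf_map`: `power` (freq x time), `freqs`,
#'   `times`, `valid` (logical freq x time), `normalized`
#' @export
#' @examples
#' x <- time_series(sin(2 * pi * 20 * seq(0, 12, by = 1 / 250)), rate = 250)
#' tf <- morlet_tf(x, freqs = 10:30)
morlet_tf <- function(lfp, n_cycles = 8, freqs = 1:90, out_rate = 20) {
  stopifnot(inherits(lfp, "lfp_ts"))
  x <- lfp$data[, 1]
  rate <- lfp$rate
  n <- length(x)
  if (max(freqs) >= rate / 2) stop("analysis frequencies must lie below Nyquist")
  if (n / rate < n_cycles / min(freqs)) {
    stop(sprintf("signal too short for %g cycles at %g Hz", n_cycles, min(freqs)))
  }
  pad <- min(n - 1, ceiling(n_cycles / (2 * min(freqs)) * rate))
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  n2 <- stats::nextn(length(xp) + pad, c(2, 3, 5))
  xp <- c(xp, numeric(n2 - length(xp)))
  X <- stats::fft(xp)
  fgrid <- (seq_len(n2) - 1) * rate / n2
  pos <- fgrid <= rate / 2        # one-sided (analytic) part
  # sigma_t = n_cycles / (2 pi f); frequency response exp(-2 pi^2 sigma_t^2 (v - f)^2)
  M <- matrix(0i, n2, length(freqs))
  for (j in seq_along(freqs)) {
    st <- n_cycles / (2 * pi * freqs[j])
    h <- numeric(n2)
    h[pos] <- 2 * exp(-2 * pi^2 * st^2 * (fgrid[pos] - freqs[j])^2)
    h[1] <- 0
    M[, j] <- h * X
  }
  Z <- stats::mvfft(M, inverse = TRUE)[(pad + 1):(pad + n), , drop = FALSE] / n2
  pw <- Re(Z)^2 + Im(Z)^2   # = A^2 for a sine of amplitude A at the centre

  # bin-average onto the output grid
  t_rel <- (seq_len(n) - 1) / rate
  bin <- round(t_rel * out_rate)
  nt <- max(bin) + 1
  counts <- tabulate(bin + 1, nbins = nt)
  agg <- rowsum(pw, group = bin, reorder = TRUE) / counts
  times <- lfp$t0 + (seq_len(nt) - 1) / out_rate
  t_end <- lfp$t0 + (n - 1) / rate

  valid <- matrix(FALSE, length(freqs), nt)
  for (j in seq_along(freqs)) {
    h <- n_cycles / (2 * freqs[j])
    valid[j, ] <- times >= lfp$t0 + h & times <= t_end - h
  }
  structure(list(power = t(agg), freqs = freqs, times = times, valid = valid,
                 normalized = FALSE),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<time-frequency map> %d freqs (%g-%g Hz) x %d times (%.2f-%.2f s)%s\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
              min(x$times), max(x$times),
              if (x$normalized) ", sum-rescaled" else ""))
  invisible(x)
}

#' Sum-rescale a time-frequency map to a reference band
#'
#' Divides each time slice by the summed power over the reference band
#' (53-90 Hz by default), making spectra comparable across hemispheres with
#' different electrode impedances / signal-to-noise ratios. After rescaling
#' the reference-band sum is exactly 1 at every time point.
#'
#' @param tf a [morlet_tf()] map
#' @param ref_band numeric length-2 reference band in Hz (inclusive)
#' @return the rescaled `tf_map`
#' @export
normalize_sum_rescale <- function(tf, ref_band = c(53, 90)) {
  stopifnot(inherits(tf, "tf_map"))
  sel <- tf$freqs >= ref_band[1] & tf$freqs <= ref_band[2]
  if (!any(sel)) stop("reference band outside the frequency grid")
  s <- colSums(tf$power[sel, , drop = FALSE])
  any_valid <- apply(tf$valid, 2, any)
  bad <- which(s <= 0 & any_valid)
  if (length(bad)) {
    stop("zero reference-band power at time index ", bad[1],
         " (t = ", tf$times[bad[1]], " s)")
  }
  s[s <= 0] <- 1
  tf$power <- sweep(tf$power, 2, s, "/")
  tf$normalized <- TRUE
  tf
}

new_power_spectrum <- function(power, freqs, state, n, condition = NULL) {
  structure(list(power = as.numeric(power), freqs = freqs, state = state,
                 condition = condition, n_samples_averaged = n),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<%s power spectrum>%s %d freqs (%g-%g Hz), %d samples averaged\n",
              x$state,
              if (is.null(x$condition)) "" else paste0(" ", format(x$condition)),
              length(x$freqs), min(x$freqs), max(x$freqs), x$n_samples_averaged))
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, log = "y", ...) {
  graphics::plot(x$freqs, x$power, type = "l", log = log,
                 xlab = "frequency (Hz)", ylab = "normalized power", ...)
  invisible(x)
}

#' Rest-state power spectrum
#'
#' Averages the time-frequency map over the first `duration` seconds of
#' movement-free, edge-valid time inside the rest window.
#'
#' @param tf a (normalised) `tf_map`
#' @param rest_window numeric length-2 `c(start, end)` in s
#' @param movement_mask optional interval matrix of times to exclude
#' @param duration seconds to average (default 30)
#' @return a `power_spectrum` with `state = "rest"`
#' @export
rest_spectrum <- function(tf, rest_window, movement_mask = NULL, duration = 30) {
  stopifnot(inherits(tf, "tf_map"))
  ok <- apply(tf$valid, 2, all) &
    tf$times >= rest_window[1] & tf$times <= rest_window[2]
  if (!is.null(movement_mask) && nrow(movement_mask)) {
    ok <- ok & !in_intervals(tf$times, movement_mask)
  }
  need <- round(duration * 1 / stats::median(diff(tf$times)))
  idx <- which(ok)
  if (length(idx) < need) {
    stop(sprintf("only %.1f s of movement-free rest available; %g s required",
                 length(idx) * stats::median(diff(tf$times)), duration))
  }
  idx <- idx[seq_len(need)]
  new_power_spectrum(rowMeans(tf$power[, idx, drop = FALSE]), tf$freqs,
                     "rest", length(idx))
}

#' Movement-state power spectrum
#'
#' Averages the time-frequency map over the union of per-tap movement
#' epochs, so that inter-tap pauses and the post-movement beta rebound do
#' not enter the movement estimate. Averaging is per frequency over the
#' edge-valid epoch samples.
#'
#' @param tf a (normalised) `tf_map`
#' @param epochs a [build_movement_epochs()] object (or an interval matrix)
#' @return a `power_spectrum` with `state = "movement"`
#' @export
movement_spectrum <- function(tf, epochs) {
  stopifnot(inherits(tf, "tf_map"))
  iv <- if (inherits(epochs, "movement_epochs")) epochs$intervals else epochs
  if (is.null(iv) || nrow(iv) == 0) stop("no movement epochs")
  inm <- in_intervals(tf$times, iv)
  if (!any(inm)) stop("no time-frequency samples inside the movement epochs")
  pw <- numeric(length(tf$freqs))
  counts <- integer(length(tf$freqs))
  for (j in seq_along(tf$freqs)) {
    sel <- inm & tf$valid[j, ]
    counts[j] <- sum(sel)
    pw[j] <- if (counts[j]) mean(tf$power[j, sel]) else NA_real_
  }
  new_power_spectrum(pw, tf$freqs, "movement", min(counts))
}

#' Locate the beta peak of a rest spectrum
#'
#' Fits a log-log linear aperiodic background over `fit_range` excluding the
#' search band, and returns the frequency of the largest background-detrended
#' power inside the band (10-35 Hz by default). Ties break toward the lower
#' frequency; if no point rises more than `min_prominence` log units above
#' the background fit, the `no_peak` flag is set (with a warning) and the
#' band minimum is returned.
#'
#' @param spec a `power_spectrum`
#' @param band numeric length-2 search band in Hz
#' @param fit_range frequency range used for the background fit
#' @param min_prominence minimal detrended log-power for a real peak
#' @return an object of class `beta_peak`: `freq`, `amplitude` (normalised
#'   power at the peak), `detrended`, `search_band`, `no_peak`
#' @export
find_beta_peak <- function(spec, band = c(10, 35), fit_range = c(5, 45),
                           min_prominence = 0.1) {
  stopifnot(inherits(spec, "power_spectrum"))
  f <- spec$freqs
  if (band[1] < min(f) || band[2] > max(f)) stop("search band outside spectrum")
  p <- pmax(spec$power, max(spec$power, na.rm = TRUE) * 1e-12 + 1e-300)
  fit_sel <- f >= fit_range[1] & f <= fit_range[2] & !(f >= band[1] & f <= band[2])
  fit <- stats::lm(lp ~ lf, data = data.frame(lp = log(p[fit_sel]),
                                              lf = log(f[fit_sel])))
  in_band <- which(f >= band[1] & f <= band[2])
  bg <- stats::predict(fit, newdata = data.frame(lf = log(f[in_band])))
  det <- log(p[in_band]) - bg
  i <- which.max(det)   # first maximum = lowest frequency on ties
  no_peak <- det[i] < min_prominence
  if (no_peak) {
    warning("no clear beta peak above the aperiodic background")
    i <- 1L
  }
  structure(list(freq = f[in_band][i], amplitude = spec$power[in_band][i],
                 detrended = det[i], search_band = band, no_peak = no_peak),
            class = "beta_peak")
}

#' @export
print.beta_peak <- function(x, ...) {
  cat(sprintf("<beta peak> %g Hz (normalized power %.4g)%s\n", x$freq,
              x$amplitude, if (x$no_peak) " [no clear peak]" else ""))
  invisible(x)
}

#' Canonical beta band powers of a spectrum
#'
#' Mean normalised power over low beta (13-20 Hz, the 20 Hz bin excluded)
#' and high beta (20-35 Hz inclusive), so the 20 Hz bin is counted once.
#'
#' @param spec a `power_spectrum`
#' @param low,high band limits in Hz
#' @return list with `low_beta` and `high_beta`
#' @export
band_power <- function(spec, low = c(13, 20), high = c(20, 35)) {
  stopifnot(inherits(spec, "power_spectrum"))
  f <- spec$freqs
  if (min(f) > low[1] || max(f) < high[2]) stop("spectrum must cover 13-35 Hz")
  list(low_beta = mean(spec$power[f >= low[1] & f < low[2]]),
       high_beta = mean(spec$power[f >= high[1] & f <= high[2]]))
}
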
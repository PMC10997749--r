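# LFP cleaning: drift/DBS-artifact band-pass, line-noise notch, R-peak
# detection and ECG template subtraction.

# Butterworth corner placement so that the forward-backward (squared
# magnitude) digital response is -3 dB at the nominal corner `f`. Works in
# the bilinear-warped domain, so it stays exact near Nyquist.
ff_corner <- function(f, rate, order, type) {
  a <- (sqrt(2) - 1)^(1 / (2 * order))   # single-pass -1.5 dB point
  w <- tan(pi * f / rate)
  wc <- if (type == "low") w / a else w * a
  atan(wc) * rate / pi
}

#' Band-pass filter an LFP recording (5-90 Hz by default)
#'
#' Zero-phase (forward-backward) Butterworth high- and low-pass, used to
#' reduce movement drift and stimulation artifacts. Corners are pre-warped so
#' the combined zero-phase response is -3 dB at `low` and `high`.
#'
#' @param lfp an `lfp_ts`
#' @param low,high corner frequencies in Hz
#' @param order Butterworth order of each single-pass section
#' @return the filtered `lfp_ts` (same length)
#' @export
bandpass_lfp <- function(lfp, low = 5, high = 90, order = 4) {
  stopifnot(inherits(lfp, "lfp_ts"))
  nyq <- lfp$rate / 2
  if (high >= nyq) stop("sampling rate too low for the requested low-pass corner")
  hp <- signal::butter(order, ff_corner(low, lfp$rate, order, "high") / nyq,
                       type = "high")
  lp <- signal::butter(order, ff_corner(high, lfp$rate, order, "low") / nyq,
                       type = "low")
  pad <- 8 * lfp$rate / low
  ts_apply(lfp, function(col) {
    filtfilt_pad(lp, filtfilt_pad(hp, col, pad), pad)
  })
}

#' Notch out line noise (48-52 Hz by default)
#'
#' Zero-phase Butterworth band-stop.
#'
#' @param lfp an `lfp_ts`
#' @param band numeric length-2 stop band in Hz
#' @param order band-stop order of the single-pass section
#' @return the filtered `lfp_ts`
#' @export
notch_line <- function(lfp, band = c(48, 52), order = 2) {
  stopifnot(inherits(lfp, "lfp_ts"))
  nyq <- lfp$rate / 2
  if (nyq <= band[2]) stop("sampling rate too low for the notch band")
  bs <- signal::butter(order, band / nyq, type = "stop")
  pad <- 2 * lfp$rate
  ts_apply(lfp, function(col) filtfilt_pad(bs, col, pad))
}

#' QRS annotation
#'
#' @param r_peak_times strictly increasing R-peak times (s)
#' @param epoch_half_width epoch half width in ms
#' @param template optional averaged QRS epoch (signal units)
#' @return an object of class `qrs_annotation`
#' @export
qrs_annotation <- function(r_peak_times, epoch_half_width = 200, template = NULL) {
  if (length(r_peak_times) > 1) {
    if (any(diff(r_peak_times) <= 0)) stop("r_peak_times must be strictly increasing")
    if (any(diff(r_peak_times) <= 0.25)) stop("inter-peak intervals must exceed 250 ms")
  }
  structure(list(r_peak_times = r_peak_times,
                 epoch_half_width = epoch_half_width, template = template),
            class = "qrs_annotation")
}

#' @export
print.qrs_annotation <- function(x, ...) {
  cat(sprintf("<qrs annotation> %d R-peaks, epoch half width %g ms\n",
              length(x$r_peak_times), x$epoch_half_width))
  invisible(x)
}

#' Detect R-peaks of cardiac contamination in an LFP recording
#'
#' Emphasises the cardiac complex with a zero-phase band-pass (6-12 Hz by
#' default, where the energy of device-filtered QRS complexes concentrates
#' while beta oscillations contribute little), squares the result, and picks
#' local maxima above an adaptive threshold (median + k * MAD of the squared
#' signal) with a minimum separation. Candidates are then screened for
#' cardiac plausibility: heights must reach a fixed fraction of the robust
#' beat amplitude, every peak needs a neighbour within the physiological
#' inter-beat range, and the inter-beat rhythm must be regular (bounded
#' robust coefficient of variation); an implausible train is returned as an
#' empty annotation with a warning.
#'
#' @param lfp a band-passed single-channel `lfp_ts`
#' @param emphasis_band band-pass emphasising the cardiac complex (Hz)
#' @param k threshold in MADs above the median of the squared signal
#' @param min_distance minimum inter-peak separation (s)
#' @param max_interval peaks with no neighbour within this interval (s) are
#'   dropped
#' @param height_fraction keep peaks at least this fraction of the 90th
#'   height percentile
#' @param max_rhythm_cv maximal MAD/median of inter-beat intervals for a
#'   plausible cardiac rhythm
#' @return a [qrs_annotation()]; empty (with a warning) when no plausible
#'   beat train is found
#' @export
detect_r_peaks <- function(lfp, emphasis_band = c(6, 12), k = 4,
                           min_distance = 0.4, max_interval = 1.5,
                           height_fraction = 0.25, max_rhythm_cv = 0.2) {
  stopifnot(inherits(lfp, "lfp_ts"))
  x <- lfp$data[, 1]
  nyq <- lfp$rate / 2
  bp <- signal::butter(3, emphasis_band / nyq, type = "pass")
  e <- filtfilt_pad(bp, x, lfp$rate)^2
  thr <- stats::median(e) + k * stats::mad(e)
  n <- length(e)
  no_ecg <- function(msg) {
    warning("no plausible cardiac beat train detected (", msg,
            "); returning empty annotation")
    qrs_annotation(numeric(0))
  }
  if (thr <= 0 || all(e <= thr)) return(no_ecg("flat signal"))
  is_max <- c(FALSE, e[2:(n - 1)] > e[1:(n - 2)] & e[2:(n - 1)] >= e[3:n], FALSE)
  cand <- which(is_max & e > thr)
  # greedy: accept highest peaks first, enforce minimum distance
  cand <- cand[order(e[cand], decreasing = TRUE)]
  acc <- integer(0)
  min_samp <- min_distance * lfp$rate
  for (i in cand) {
    if (!length(acc) || all(abs(acc - i) >= min_samp)) acc <- c(acc, i)
  }
  acc <- sort(acc)
  # amplitude screening against the robust beat level
  lev <- stats::quantile(e[acc], 0.9, names = FALSE)
  acc <- acc[e[acc] >= height_fraction * lev]
  tpk <- ts_times(lfp)[acc]
  if (length(tpk) > 1) {
    gaps <- diff(tpk)
    keep <- vapply(seq_along(tpk), function(i) {
      (i > 1 && gaps[i - 1] <= max_interval) ||
        (i < length(tpk) && gaps[i] <= max_interval)
    }, logical(1))
    tpk <- tpk[keep]
  }
  if (length(tpk) < 3) return(no_ecg("fewer than 3 peaks"))
  iv <- diff(tpk)
  med <- stats::median(iv)
  cv <- stats::mad(iv) / med
  if (med < min_distance || med > max_interval || cv > max_rhythm_cv) {
    return(no_ecg(sprintf("irregular rhythm, interval %.2f s, cv %.2f", med, cv)))
  }
  qrs_annotation(tpk)
}

# Periodogram-based power of the cardiac harmonic comb, in excess of the
# locally interpolated background (off-comb bins half-way between harmonics).
cardiac_comb_power <- function(x, rate, f0, fmax = 35, half_width = 0.25) {
  n <- length(x)
  n2 <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x - mean(x), numeric(n2 - n)))
  pw <- (Mod(X[seq_len(floor(n2 / 2) + 1)])^2) / (n * n2)
  fr <- rfft_freqs(n2, rate)
  harmonics <- f0 * seq_len(floor(fmax / f0))
  harmonics <- harmonics[harmonics >= 1]
  tot <- 0
  for (h in harmonics) {
    on <- fr >= h - half_width & fr <= h + half_width
    off <- (fr >= h - f0 / 2 - half_width & fr <= h - f0 / 2 + half_width) |
      (fr >= h + f0 / 2 - half_width & fr <= h + f0 / 2 + half_width)
    excess <- sum(pw[on]) - sum(pw[off]) / 2
    tot <- tot + max(excess, 0)
  }
  tot
}

# Band variance from the periodogram.
periodogram_band_power <- function(x, rate, lo, hi) {
  n <- length(x)
  n2 <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x - mean(x), numeric(n2 - n)))
  pw <- (Mod(X[seq_len(floor(n2 / 2) + 1)])^2) / (n * n2)
  fr <- rfft_freqs(n2, rate)
  2 * sum(pw[fr >= lo & fr < hi])
}

#' Remove cardiac contamination by template subtraction
#'
#' QRS epochs are taken 200 ms before and after each detected R-peak, the
#' pointwise average of all complete epochs forms the template, and the
#' template is subtracted from the signal inside every epoch; samples outside
#' epochs are untouched. Epochs extending past the signal edges are skipped
#' and counted.
#'
#' @param lfp a single-channel `lfp_ts`
#' @param qrs a [qrs_annotation()] with at least one R-peak
#' @return list with elements `lfp` (cleaned series), `report` (a
#'   `cleaning_report`: peak count, cardiac-comb and beta-band power before
#'   and after, skipped-epoch count, severity flag), and `qrs` (the
#'   annotation with the template filled in)
#' @export
subtract_ecg_template <- function(lfp, qrs) {
  stopifnot(inherits(lfp, "lfp_ts"), inherits(qrs, "qrs_annotation"))
  if (length(qrs$r_peak_times) == 0) stop("QRS annotation is empty")
  x <- lfp$data[, 1]
  n <- length(x)
  half <- round(qrs$epoch_half_width / 1000 * lfp$rate)
  centers <- round((qrs$r_peak_times - lfp$t0) * lfp$rate) + 1
  ok <- centers - half >= 1 & centers + half <= n
  n_skipped <- sum(!ok)
  centers <- centers[ok]
  if (length(centers) == 0) stop("no complete QRS epoch inside the signal")
  epochs <- vapply(centers, function(c0) x[(c0 - half):(c0 + half)],
                   numeric(2 * half + 1))
  template <- rowMeans(epochs)
  y <- x
  for (c0 in centers) {
    idx <- (c0 - half):(c0 + half)
    y[idx] <- y[idx] - template
  }
  f0 <- if (length(qrs$r_peak_times) > 1) {
    1 / stats::median(diff(qrs$r_peak_times))
  } else 70 / 60   # nominal rate when a single beat is annotated
  art_before <- cardiac_comb_power(x, lfp$rate, f0)
  art_after <- cardiac_comb_power(y, lfp$rate, f0)
  beta_before <- periodogram_band_power(x, lfp$rate, 13, 35)
  beta_after <- periodogram_band_power(y, lfp$rate, 13, 35)
  ratio <- art_before / max(beta_before, .Machine$double.eps)
  severity <- if (ratio < 0.1) "not present" else if (ratio < 0.75) "not severe" else "severe"
  report <- structure(
    list(n_r_peaks = length(centers), n_skipped_epochs = n_skipped,
         artifact_power_before = art_before, artifact_power_after = art_after,
         beta_power_before = beta_before, beta_power_after = beta_after,
         severity_flag = severity),
    class = "cleaning_report"
  )
  out <- lfp
  out$data[, 1] <- y
  qrs$template <- template
  list(lfp = out, report = report, qrs = qrs)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("<cleaning report> %d R-peaks (%d epochs skipped); artifact: %s\n",
              x$n_r_peaks, x$n_skipped_epochs, x$severity_flag))
  cat(sprintf("  cardiac comb power %.4g -> %.4g; 13-35 Hz power %.4g -> %.4g\n",
              x$artifact_power_before, x$artifact_power_after,
              x$beta_power_before, x$beta_power_after))
  invisible(x)
}

#' Standard LFP preprocessing chain
#'
#' Band-pass (5-90 Hz), notch (48-52 Hz), then ECG detection and template
#' subtraction. With `ecg_clean = "auto"` the subtraction result is kept only
#' when the artifact severity is at least "not severe", mirroring per-patient
#' artifact annotation practice.
#'
#' @param lfp raw single-channel `lfp_ts` at 250 Hz
#' @param ecg_clean one of `"auto"`, `"on"`, `"off"`
#' @return list with `lfp` (cleaned series) and `report` (a
#'   `cleaning_report`, or `NULL` when cleaning was off or no peaks found)
#' @export
preprocess_lfp <- function(lfp, ecg_clean = c("auto", "on", "off")) {
  ecg_clean <- match.arg(ecg_clean)
  y <- notch_line(bandpass_lfp(lfp))
  report <- NULL
  if (ecg_clean != "off") {
    qrs <- withCallingHandlers(
      detect_r_peaks(y),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (length(qrs$r_peak_times) >= 3) {
      cleaned <- subtract_ecg_template(y, qrs)
      report <- cleaned$report
      if (ecg_clean == "on" || report$severity_flag != "not present") {
        y <- cleaned$lfp
      }
    }
  }
  list(lfp = y, report = report)
}
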
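# Tap detection in accelerometer traces and behavioural metrics.

# Project a multi-channel accelerometer onto its principal axis over the
# tapping blocks; sign chosen so opening peaks (largest excursions) are
# positive.
principal_axis <- function(accel, spans) {
  if (ncol(accel$data) == 1) {
    v <- accel$data[, 1]
  } else {
    tt <- ts_times(accel)
    sel <- in_intervals(tt, spans)
    if (!any(sel)) sel <- rep(TRUE, length(tt))
    pc <- stats::prcomp(accel$data[sel, , drop = FALSE], center = TRUE)
    v <- as.numeric(scale(accel$data, center = pc$center, scale = FALSE) %*%
                      pc$rotation[, 1])
  }
  tt <- ts_times(accel)
  sel <- in_intervals(tt, spans)
  ref <- if (any(sel)) v[sel] else v
  # opening accelerations are sharper and larger than closing ones, so the
  # in-block signal is positively skewed on the correctly signed axis
  if (mean((ref - mean(ref))^3) < 0) v <- -v
  v
}

#' Detect taps in a prepared accelerometer trace
#'
#' Works on the principal-axis projection of the (250 Hz, high-passed)
#' trace. Opening peaks are positive local maxima above a prominence
#' threshold with a minimum separation; for each opening peak the closing
#' peak is the most negative sample before the next opening peak, and the
#' tap end is the first zero-crossing after the closing peak. Events outside
#' the given block spans are discarded.
#'
#' @param accel a prepared `lfp_ts` (see [prepare_accelerometer()])
#' @param spans matrix of tapping-block spans (`start`, `end` in s), e.g.
#'   [block_spans()]
#' @param prominence detection threshold in m/s^2; by default the larger of
#'   5 x MAD of the out-of-block (rest) signal and 0.4 x the 99.5th
#'   percentile of the in-block signal, so it adapts to sensor noise without
#'   being inflated by dense tapping
#' @param min_separation minimum separation between opening peaks (s)
#' @return data.frame of tap events: `open_peak_time`, `open_peak_accel`,
#'   `close_peak_time`, `tap_end_time`, `onset_time` (zero-crossing before
#'   the opening peak), `block`
#' @export
detect_tap_peaks <- function(accel, spans, prominence = NULL,
                             min_separation = 0.15) {
  stopifnot(inherits(accel, "lfp_ts"))
  v <- principal_axis(accel, spans)
  tt <- ts_times(accel)
  empty <- data.frame(open_peak_time = numeric(0), open_peak_accel = numeric(0),
                      close_peak_time = numeric(0), tap_end_time = numeric(0),
                      onset_time = numeric(0), block = integer(0))
  inb <- in_intervals(tt, spans)
  if (!any(inb)) return(empty)
  if (is.null(prominence)) {
    noise <- if (any(!inb)) stats::mad(v[!inb]) else stats::mad(v)
    peak_level <- stats::quantile(v[inb], 0.995, names = FALSE)
    prominence <- max(5 * noise, 0.4 * peak_level)
  }
  if (prominence <= 0 || all(v[inb] <= prominence)) return(empty)
  n <- length(v)
  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE)
  cand <- which(is_max & v > prominence & inb)
  cand <- cand[order(v[cand], decreasing = TRUE)]
  acc <- integer(0)
  min_samp <- min_separation * accel$rate
  for (i in cand) {
    if (!length(acc) || all(abs(acc - i) >= min_samp)) acc <- c(acc, i)
  }
  acc <- sort(acc)
  if (!length(acc)) return(empty)

  blk <- integer(length(acc))
  for (b in seq_len(nrow(spans))) {
    blk[tt[acc] >= spans[b, 1] & tt[acc] <= spans[b, 2]] <- b
  }
  events <- lapply(seq_along(acc), function(j) {
    i <- acc[j]
    # search window: up to the next opening peak (or block end)
    i_hi <- if (j < length(acc) && blk[j + 1] == blk[j]) acc[j + 1] - 1 else {
      min(n, which(tt >= spans[blk[j], 2])[1], na.rm = TRUE)
    }
    if (is.na(i_hi) || i_hi <= i) i_hi <- min(n, i + round(accel$rate))
    seg <- v[i:i_hi]
    i_close <- i + which.min(seg) - 1
    after <- v[i_close:i_hi]
    zc <- which(after >= 0)[1]
    i_end <- if (is.na(zc)) i_hi else i_close + zc - 1
    # onset: last zero-crossing before the opening peak
    before <- v[max(1, i - round(accel$rate)):i]
    zb <- which(rev(before) <= 0)[1]
    i_on <- if (is.na(zb)) max(1, i - round(accel$rate)) else i - zb + 2
    data.frame(open_peak_time = tt[i], open_peak_accel = v[i],
               close_peak_time = tt[i_close], tap_end_time = tt[i_end],
               onset_time = tt[min(i_on, i)], block = blk[j])
  })
  do.call(rbind, events)
}

#' Behavioural metrics of one tapping block
#'
#' Number of taps, tapping frequency (taps per second of block duration) and
#' mean peak opening acceleration. An empty block yields zero metrics with
#' `empty = TRUE`.
#'
#' @param events tap-event data.frame from [detect_tap_peaks()]
#' @param span numeric length-2 block span (s)
#' @return one-row data.frame: `n_taps`, `tapping_frequency`,
#'   `mean_peak_acceleration`, `block_start`, `block_end`, `empty`
#' @export
compute_block_metrics <- function(events, span) {
  ev <- events[events$open_peak_time >= span[1] & events$open_peak_time <= span[2], ]
  n <- nrow(ev)
  if (n == 0) {
    return(data.frame(n_taps = 0L, tapping_frequency = 0,
                      mean_peak_acceleration = 0,
                      block_start = span[1], block_end = span[2], empty = TRUE))
  }
  data.frame(n_taps = n,
             tapping_frequency = n / (span[2] - span[1]),
             mean_peak_acceleration = mean(ev$open_peak_accel),
             block_start = span[1], block_end = span[2], empty = FALSE)
}

#' Mean duration of a full tap
#'
#' Averages, over events, the time from the tap onset to the zero-crossing
#' of acceleration after the closing peak (before the fingers meet). The
#' onset is either the zero-crossing preceding the opening peak (default) or
#' the opening peak itself.
#'
#' @param events tap-event data.frame from [detect_tap_peaks()]
#' @param onset `"zero_crossing"` or `"open_peak"`
#' @return list with `mean_ms` and `sd_ms`
#' @export
estimate_tap_duration <- function(events, onset = c("zero_crossing", "open_peak")) {
  onset <- match.arg(onset)
  if (nrow(events) == 0) stop("no tap events")
  start <- if (onset == "zero_crossing") events$onset_time else events$open_peak_time
  d <- (events$tap_end_time - start) * 1000
  list(mean_ms = mean(d), sd_ms = if (length(d) > 1) stats::sd(d) else 0)
}

#' Build movement epochs around opening peaks
#'
#' One epoch per opening peak, centred on it, of width `tap_duration`;
#' overlapping epochs are merged. Used as the averaging mask for
#' movement-state spectra, so that inter-tap pauses and post-movement beta
#' rebound are excluded.
#'
#' @param events tap-event data.frame from [detect_tap_peaks()]
#' @param tap_duration epoch width in ms
#' @return an object of class `movement_epochs`: list with `centers` (s),
#'   `half_width` (ms), `intervals` (merged epoch matrix)
#' @export
build_movement_epochs <- function(events, tap_duration) {
  if (tap_duration <= 0) stop("tap_duration must be > 0")
  centers <- events$open_peak_time
  hw <- tap_duration / 2 / 1000
  iv <- if (length(centers)) cbind(centers - hw, centers + hw) else
    matrix(numeric(0), ncol = 2)
  structure(list(centers = centers, half_width = tap_duration / 2,
                 mean_tap_duration = tap_duration,
                 intervals = merge_intervals(iv)),
            class = "movement_epochs")
}

#' @export
print.movement_epochs <- function(x, ...) {
  cat(sprintf("<movement epochs> %d taps, half width %.1f ms, %.2f s total mask\n",
              length(x$centers), x$half_width,
              if (nrow(x$intervals)) sum(x$intervals[, 2] - x$intervals[, 1]) else 0))
  invisible(x)
}

#' Behavioural metrics of a whole session
#'
#' Runs tap detection over all blocks, computes per-block metrics and their
#' across-block averages, the mean tap duration, and the movement epochs.
#'
#' @param accel prepared accelerometer `lfp_ts`
#' @param paradigm a [paradigm_spec()]
#' @param ... passed to [detect_tap_peaks()]
#' @return list with `events`, `per_block` (data.frame), `summary` (averaged
#'   metrics), `tap_duration`, `epochs`
#' @export
session_movement_metrics <- function(accel, paradigm, ...) {
  spans <- block_spans(paradigm)
  events <- detect_tap_peaks(accel, spans, ...)
  per_block <- do.call(rbind, lapply(seq_len(nrow(spans)), function(b) {
    cbind(block = b, compute_block_metrics(events, spans[b, ]))
  }))
  summary <- data.frame(
    n_taps = mean(per_block$n_taps),
    tapping_frequency = mean(per_block$tapping_frequency),
    mean_peak_acceleration = mean(per_block$mean_peak_acceleration[!per_block$empty])
  )
  td <- if (nrow(events)) estimate_tap_duration(events)$mean_ms else
    paradigm$tap_duration
  list(events = events, per_block = per_block, summary = summary,
       tap_duration = td, epochs = build_movement_epochs(events, td))
}
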
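#' Uniformly sampled multi-channel time series
#'
#' The basic carrier for LFP and accelerometer data: a samples x channels
#' matrix with a sampling rate, a start time on the session time base, channel
#' names and a unit label.
#'
#' @param data numeric vector or samples x channels matrix
#' @param rate sampling rate in Hz (> 0)
#' @param t0 time of the first sample in seconds
#' @param channel_names character vector, one per column
#' @param units unit label (e.g. "uV", "m/s^2")
#' @return an object of class `lfp_ts`
#' @export
#' @examples
#' x <- time_series(sin(2 * pi * 5 * seq(0, 1, by = 1 / 250)), rate = 250)
#' ts_duration(x)
time_series <- function(data, rate, t0 = 0, channel_names = NULL, units = "a.u.") {
  if (is.vector(data)) data <- matrix(data, ncol = 1)
  data <- as.matrix(data)
  stopifnot(is.numeric(rate), length(rate) == 1L)
  if (rate <= 0) stop("rate must be > 0")
  if (!all(is.finite(data))) stop("data must be finite")
  if (is.null(channel_names)) {
    channel_names <- if (ncol(data) == 1) "ch1" else paste0("ch", seq_len(ncol(data)))
  }
  if (length(channel_names) != ncol(data)) {
    stop("channel_names length must equal channel count")
  }
  structure(
    list(data = data, rate = rate, t0 = t0,
         channel_names = as.character(channel_names), units = units),
    class = "lfp_ts"
  )
}

#' @export
print.lfp_ts <- function(x, ...) {
  cat(sprintf("<time series> %d samples x %d channel(s) @ %g Hz, t0 = %.4g s, units = %s\n",
              nrow(x$data), ncol(x$data), x$rate, x$t0, x$units))
  cat(sprintf("  duration %.3f s; channels: %s\n",
              ts_duration(x), paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' Sample times of a time series
#' @param x an `lfp_ts` object
#' @return numeric vector of times in seconds (session time base)
#' @export
ts_times <- function(x) x$t0 + (seq_len(nrow(x$data)) - 1) / x$rate

#' Duration of a time series in seconds
#' @param x an `lfp_ts` object
#' @return duration in seconds
#' @export
ts_duration <- function(x) nrow(x$data) / x$rate

#' Crop a time series to a time window
#' @param x an `lfp_ts` object
#' @param from,to window bounds in seconds on the session time base
#' @return the cropped `lfp_ts`
#' @export
ts_crop <- function(x, from, to) {
  t <- ts_times(x)
  keep <- t >= from - 1e-9 & t <= to + 1e-9
  if (!any(keep)) stop("crop window leaves no samples")
  time_series(x$data[keep, , drop = FALSE], x$rate, t0 = t[which(keep)[1]],
              channel_names = x$channel_names, units = x$units)
}

#' @export
plot.lfp_ts <- function(x, channel = 1, ...) {
  graphics::plot(ts_times(x), x$data[, channel], type = "l",
                 xlab = "time (s)", ylab = x$units,
                 main = x$channel_names[channel], ...)
  invisible(x)
}

# Apply a function to every channel, returning a new lfp_ts.
ts_apply <- function(x, f) {
  y <- apply(x$data, 2, f)
  if (is.vector(y)) y <- matrix(y, ncol = ncol(x$data))
  time_series(y, x$rate, x$t0, x$channel_names, x$units)
}
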
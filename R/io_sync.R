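# Session file IO, accelerometer preparation and stream alignment.

#' Write a session to a directory
#'
#' One comma-separated file per stream (`lfp.csv`, `accel.csv`; columns
#' `time_s` then one column per channel) plus a `session.json` sidecar with
#' rates, units, condition label, paradigm timing, clock offset and, when
#' supplied, the generator ground truth.
#'
#' @param session a [session_recording()]
#' @param path output directory (created if missing)
#' @param ground_truth optional ground-truth list from [generate_session()]
#' @return `path`, invisibly
#' @export
write_session <- function(session, path, ground_truth = NULL) {
  stopifnot(inherits(session, "session_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(ts, file) {
    df <- data.table::data.table(time_s = ts_times(ts))
    for (i in seq_along(ts$channel_names)) {
      df[[ts$channel_names[i]]] <- ts$data[, i]
    }
    data.table::fwrite(df, file.path(path, file))
  }
  wr(session$lfp, "lfp.csv")
  wr(session$accel, "accel.csv")
  sidecar <- list(
    condition = format(session$condition),
    clock_offset = session$clock_offset,
    paradigm = unclass(session$paradigm),
    lfp = list(rate = session$lfp$rate, t0 = session$lfp$t0,
               units = session$lfp$units, channels = session$lfp$channel_names),
    accel = list(rate = session$accel$rate, t0 = session$accel$t0,
                 units = session$accel$units, channels = session$accel$channel_names)
  )
  if (!is.null(ground_truth)) sidecar$ground_truth <- ground_truth
  jsonlite::write_json(sidecar, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a session from a directory
#'
#' Inverse of [write_session()]. Rates and units are taken from the sidecar;
#' the time columns are checked for monotonicity and consistency with the
#' declared rates.
#'
#' @param path session directory
#' @return a [session_recording()]; any stored ground truth is attached as
#'   attribute `"ground_truth"`
#' @export
read_session <- function(path) {
  sj <- file.path(path, "session.json")
  if (!file.exists(sj)) stop("missing sidecar: ", sj)
  meta <- jsonlite::read_json(sj, simplifyVector = TRUE)
  rd <- function(file, m) {
    fp <- file.path(path, file)
    if (!file.exists(fp)) stop("missing stream file: ", fp)
    df <- data.table::fread(fp)
    tcol <- df$time_s
    if (any(diff(tcol) <= 0)) stop("non-monotone time column in ", file)
    dt <- stats::median(diff(tcol))
    if (abs(dt - 1 / m$rate) > 1e-6 / m$rate + 1e-9) {
      stop(sprintf("time spacing in %s (%.6g s) inconsistent with sidecar rate %g Hz",
                   file, dt, m$rate))
    }
    time_series(as.matrix(df[, m$channels, with = FALSE]), m$rate,
                t0 = tcol[1], channel_names = m$channels, units = m$units)
  }
  lfp <- rd("lfp.csv", meta$lfp)
  accel <- rd("accel.csv", meta$accel)
  pd <- meta$paradigm
  paradigm <- paradigm_spec(pd$rest_duration, pd$n_blocks, pd$block_duration,
                            pd$interblock_rest, pd$tap_rate, pd$tap_duration)
  out <- session_recording(lfp, accel, condition_label(meta$condition),
                           paradigm, clock_offset = meta$clock_offset)
  if (!is.null(meta$ground_truth)) attr(out, "ground_truth") <- meta$ground_truth
  out
}

# Zero-phase decimation by an integer factor: a Blackman-windowed sinc
# anti-alias low-pass (cutoff 0.8 of the post-decimation Nyquist, applied in
# the frequency domain so the phase is exactly zero) followed by subsampling.
decimate_channel <- function(x, q, rate) {
  y <- fft_fir_lowpass(x, rate, cutoff = 0.8 * (rate / q) / 2,
                       taps = min(2049, 2 * floor(length(x) / 4) + 1))
  y[seq(1, length(y), by = q)]
}

#' Prepare an accelerometer stream for analysis
#'
#' Downsamples to 250 Hz (zero-phase anti-alias low-pass before each
#' decimation stage) and applies a zero-phase 1 Hz high-pass, removing any
#' constant offset (gravity / sensor bias).
#'
#' @param accel an `lfp_ts` with rate >= 250 Hz (an integer multiple of 250)
#' @param target_rate output rate in Hz
#' @return the prepared `lfp_ts` at `target_rate`
#' @export
prepare_accelerometer <- function(accel, target_rate = 250) {
  stopifnot(inherits(accel, "lfp_ts"))
  if (accel$rate < target_rate) stop("accelerometer rate below ", target_rate, " Hz")
  q <- accel$rate / target_rate
  if (abs(q - round(q)) > 1e-9) stop("input rate must be an integer multiple of the target rate")
  q <- round(q)
  hp <- signal::butter(2, 1 / (target_rate / 2), type = "high")
  y <- apply(accel$data, 2, function(col) {
    col <- col - mean(col)
    if (q > 1) col <- decimate_channel(col, q, accel$rate)
    signal::filtfilt(hp, col)
  })
  time_series(y, target_rate, t0 = accel$t0, channel_names = accel$channel_names,
              units = accel$units)
}

#' Place both streams of a session on the LFP time base
#'
#' Shifts the accelerometer stream by `offset` seconds (accelerometer start
#' minus LFP start, as produced by the synchronisation procedure), then trims
#' both streams to their common support. Annotations are stored on the LFP
#' time base throughout the package, so they are untouched.
#'
#' @param session a [session_recording()]
#' @param offset signed clock offset in s; defaults to the session's stored
#'   `clock_offset`
#' @return the aligned [session_recording()] with `clock_offset = 0`
#' @export
align_streams <- function(session, offset = session$clock_offset) {
  stopifnot(inherits(session, "session_recording"))
  if (abs(offset) >= min(ts_duration(session$lfp), ts_duration(session$accel))) {
    stop("offset leaves no overlap between streams")
  }
  accel <- session$accel
  accel$t0 <- accel$t0 + offset
  lo <- max(session$lfp$t0, accel$t0)
  hi <- min(session$lfp$t0 + ts_duration(session$lfp),
            accel$t0 + ts_duration(accel))
  if (hi <= lo) stop("offset leaves no overlap between streams")
  out <- session
  out$lfp <- ts_crop(session$lfp, lo, hi - 1e-9)
  out$accel <- ts_crop(accel, lo, hi - 1e-9)
  out$clock_offset <- 0
  out
}
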
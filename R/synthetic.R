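# Ground-truthed synthetic session generator.
#
# Sessions emulate bipolar subthalamic LFP streamed from a sensing-enabled
# pulse generator (250 Hz) paired with a tri-axial finger accelerometer
# (4 kHz): 1/f background, bursty (stochastic narrow-band) beta oscillations,
# movement-locked beta suppression with a post-block rebound, ECG
# contamination, 50 Hz line noise, and a clock offset between the streams.

#' Condition label (medication x stimulation)
#'
#' @param x either a string like `"M0S1"`, or the medication state (0/1) when
#'   `stim` is also given
#' @param stim stimulation state (0/1), optional
#' @return an object of class `condition_label` with fields `med` and `stim`
#' @export
#' @examples
#' condition_label("M1S0")
#' condition_label(0, 1)
condition_label <- function(x, stim = NULL) {
  if (is.character(x)) {
    if (!grepl("^M[01]S[01]$", x)) stop("unknown condition label: ", x)
    med <- as.integer(substr(x, 2, 2))
    stim <- as.integer(substr(x, 4, 4))
  } else {
    med <- as.integer(x)
    stim <- as.integer(stim)
    if (!med %in% 0:1 || !stim %in% 0:1) stop("med and stim must be 0 or 1")
  }
  structure(list(med = med, stim = stim), class = "condition_label")
}

#' @export
format.condition_label <- function(x, ...) sprintf("M%dS%d", x$med, x$stim)

#' @export
print.condition_label <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Spectral profile of the simulated LFP
#'
#' Describes the rest-state spectrum: an aperiodic 1/f^exponent background
#' (flat below 1 Hz), a set of Gaussian-shaped oscillatory peaks realised as
#' stochastic narrow-band components, and a 50 Hz line component.
#'
#' @param background_exponent 1/f slope of the aperiodic background
#' @param background_scale standard deviation of the background component
#'   (signal units)
#' @param peaks list of peaks, each `list(center, amplitude, fwhm)`: centre
#'   frequency (Hz), component RMS amplitude (signal units), full width at
#'   half maximum (Hz)
#' @param line_noise_amp amplitude of the 50 Hz line component (signal units)
#' @return an object of class `spectral_profile`
#' @export
spectral_profile <- function(background_exponent = 1.5,
                             background_scale = 1,
                             peaks = list(
                               list(center = 17.33, amplitude = 0.6, fwhm = 4),
                               list(center = 25, amplitude = 0.42, fwhm = 5)
                             ),
                             line_noise_amp = 0.5) {
  for (p in peaks) {
    stopifnot(is.numeric(p$center), is.numeric(p$amplitude), is.numeric(p$fwhm))
    if (p$center <= 0 || p$center >= 125) stop("peak center must lie in (0, 125) Hz")
    if (p$fwhm <= 0) stop("peak fwhm must be > 0")
    if (p$amplitude < 0) stop("peak amplitude must be >= 0")
  }
  if (background_scale < 0 || line_noise_amp < 0) stop("amplitudes must be >= 0")
  structure(list(background_exponent = background_exponent,
                 background_scale = background_scale,
                 peaks = peaks, line_noise_amp = line_noise_amp),
            class = "spectral_profile")
}

#' Movement-locked modulation of beta power
#'
#' During tapping blocks the power of the signal restricted to
#' `suppression_band` is multiplied by `1 - suppression_fraction`
#' (desynchronisation); for one second after each block it is multiplied by
#' `1 + rebound_fraction` (post-movement synchronisation overshoot).
#'
#' @param suppression_band numeric length-2, `c(lo, hi)` in Hz
#' @param suppression_fraction fraction of band power removed during tapping,
#'   in `[0, 1]`
#' @param rebound_fraction post-block power overshoot fraction (>= 0)
#' @return an object of class `movement_modulation`
#' @export
movement_modulation <- function(suppression_band = c(18, 28),
                                suppression_fraction = 0.5,
                                rebound_fraction = 0.2) {
  stopifnot(length(suppression_band) == 2)
  if (suppression_band[1] >= suppression_band[2]) stop("suppression_band lo must be < hi")
  if (suppression_fraction < 0 || suppression_fraction > 1) {
    stop("suppression_fraction must lie in [0, 1]")
  }
  if (rebound_fraction < 0) stop("rebound_fraction must be >= 0")
  structure(list(suppression_band = suppression_band,
                 suppression_fraction = suppression_fraction,
                 rebound_fraction = rebound_fraction),
            class = "movement_modulation")
}

#' Simulated cardiac contamination
#'
#' QRS complexes are modelled as Mexican-hat (Ricker) biphasic pulses placed
#' at jittered inter-beat intervals. The width parameter is the approximate
#' full extent of the complex; the Ricker scale is `qrs_width / 4` so the
#' trough-to-trough distance is about `0.87 * qrs_width`.
#'
#' @param heart_rate beats per minute, in `[40, 150]`
#' @param qrs_amplitude peak amplitude of the complex (signal units); 0
#'   disables contamination
#' @param qrs_width approximate complex width in ms (> 0)
#' @param jitter_sd standard deviation of inter-beat intervals in ms
#' @return an object of class `ecg_model`
#' @export
ecg_model <- function(heart_rate = 70, qrs_amplitude = 4,
                      qrs_width = 120, jitter_sd = 20) {
  if (heart_rate < 40 || heart_rate > 150) stop("heart_rate must lie in [40, 150] bpm")
  if (qrs_width <= 0) stop("qrs_width must be > 0")
  if (qrs_amplitude < 0 || jitter_sd < 0) stop("amplitudes/sds must be >= 0")
  structure(list(heart_rate = heart_rate, qrs_amplitude = qrs_amplitude,
                 qrs_width = qrs_width, jitter_sd = jitter_sd),
            class = "ecg_model")
}

#' Recording paradigm timing
#'
#' One condition's session: an initial rest period followed by `n_blocks`
#' finger-tapping blocks, each followed by an inter-block rest (so the
#' defaults give 60 + 3 x (10 + 10) = 120 s in total).
#'
#' @param rest_duration initial rest in s
#' @param n_blocks number of tapping blocks
#' @param block_duration tapping block length in s
#' @param interblock_rest rest after each block in s
#' @param tap_rate taps per second during blocks
#' @param tap_duration duration of one full tap (opening + closing) in ms
#' @return an object of class `paradigm_spec`
#' @export
paradigm_spec <- function(rest_duration = 60, n_blocks = 3, block_duration = 10,
                          interblock_rest = 10, tap_rate = 1.31,
                          tap_duration = 205.4) {
  if (any(c(rest_duration, block_duration, interblock_rest, tap_duration) <= 0)) {
    stop("all durations must be > 0")
  }
  if (n_blocks < 1) stop("need at least one tapping block")
  if (tap_rate * block_duration < 1) stop("tap_rate x block_duration must be >= 1")
  structure(list(rest_duration = rest_duration, n_blocks = as.integer(n_blocks),
                 block_duration = block_duration, interblock_rest = interblock_rest,
                 tap_rate = tap_rate, tap_duration = tap_duration),
            class = "paradigm_spec")
}

#' Tapping-block time spans of a paradigm
#' @param paradigm a [paradigm_spec()]
#' @return matrix with one row per block, columns `start`, `end` (s)
#' @export
block_spans <- function(paradigm) {
  starts <- paradigm$rest_duration +
    (seq_len(paradigm$n_blocks) - 1) *
      (paradigm$block_duration + paradigm$interblock_rest)
  cbind(start = starts, end = starts + paradigm$block_duration)
}

#' Total session duration implied by a paradigm
#' @param paradigm a [paradigm_spec()]
#' @return duration in seconds
#' @export
paradigm_duration <- function(paradigm) {
  paradigm$rest_duration +
    paradigm$n_blocks * (paradigm$block_duration + paradigm$interblock_rest)
}

# Nominal tap onset times (session base): taps are spaced 1/tap_rate apart
# starting 0.1 s into each block; round(tap_rate * block_duration) per block.
paradigm_tap_onsets <- function(paradigm) {
  n_per_block <- round(paradigm$tap_rate * paradigm$block_duration)
  bs <- block_spans(paradigm)
  unlist(lapply(seq_len(nrow(bs)), function(i) {
    bs[i, 1] + 0.1 + (seq_len(n_per_block) - 1) / paradigm$tap_rate
  }))
}

# Piecewise-constant band factor evaluated on a frequency grid.
# factors: list of list(band = c(lo, hi), factor = f); multiplicative where
# bands overlap. Applied to *power*.
band_factor_profile <- function(freqs, factors) {
  f <- rep(1, length(freqs))
  for (bf in factors) {
    sel <- freqs >= bf$band[1] & freqs < bf$band[2]
    f[sel] <- f[sel] * bf$factor
  }
  f
}

# One-sided amplitude shapes (unnormalised) for profile components.
profile_shapes <- function(profile, freqs) {
  bg <- ifelse(freqs > 0, pmax(freqs, 1)^(-profile$background_exponent / 2), 0)
  bg[1] <- 0  # no DC
  pk <- lapply(profile$peaks, function(p) {
    s <- p$fwhm / (2 * sqrt(2 * log(2)))
    exp(-(freqs - p$center)^2 / (2 * s^2))
  })
  list(background = bg, peaks = pk)
}

# Variance of a shaped-noise component falling inside [lo, hi), given its
# one-sided shape and total scale (uses the same normalisation as
# shaped_noise, with optional power factors already applied).
component_band_variance <- function(amp, freqs, lo, hi, scale, pow_factor = NULL) {
  a2 <- amp^2
  tot <- sum(a2)
  if (!is.null(pow_factor)) a2 <- a2 * pow_factor
  if (tot == 0) return(0)
  sel <- freqs >= lo & freqs < hi
  scale^2 * sum(a2[sel]) / tot
}

# Movement-modulation amplitude envelope on the sample grid.
modulation_envelope <- function(tt, paradigm, modulation, ramp = 0.25,
                                rebound_window = 1) {
  env <- rep(1, length(tt))
  g_down <- sqrt(1 - modulation$suppression_fraction)
  g_up <- sqrt(1 + modulation$rebound_fraction)
  half_cos <- function(u) (1 + cos(pi * u)) / 2  # 1 -> 0 over u in [0, 1]
  bs <- block_spans(paradigm)
  for (i in seq_len(nrow(bs))) {
    s <- bs[i, 1]; e <- bs[i, 2]
    # desynchronisation onset precedes the movement block, so the whole
    # block interior (all tap epochs) sits at the suppressed level
    sel <- tt >= s - ramp & tt < s
    env[sel] <- 1 + (g_down - 1) * (1 - half_cos((tt[sel] - (s - ramp)) / ramp))
    env[tt >= s & tt < e] <- g_down
    sel <- tt >= e & tt < e + ramp
    env[sel] <- g_down + (g_up - g_down) * (1 - half_cos((tt[sel] - e) / ramp))
    sel <- tt >= e + ramp & tt < e + ramp + rebound_window
    env[sel] <- g_up
    re <- e + ramp + rebound_window
    sel <- tt >= re & tt < re + ramp
    env[sel] <- g_up + (1 - g_up) * (1 - half_cos((tt[sel] - re) / ramp))
  }
  env
}

# Full generator; returns the series plus injected ground-truth details.
generate_lfp_impl <- function(profile, modulation = NULL, ecg = NULL,
                              paradigm = paradigm_spec(), rate = 250,
                              seed = 1, band_factors = NULL) {
  stopifnot(inherits(profile, "spectral_profile"))
  for (p in profile$peaks) {
    if (p$center >= rate / 2) stop("peak center above Nyquist frequency")
  }
  total <- paradigm_duration(paradigm)
  n <- round(total * rate)
  tt <- (seq_len(n) - 1) / rate
  freqs <- rfft_freqs(n, rate)
  shapes <- profile_shapes(profile, freqs)
  pf <- if (is.null(band_factors)) NULL else band_factor_profile(freqs, band_factors)
  af <- if (is.null(pf)) NULL else sqrt(pf)

  x_bg <- with_seed(derive_seed(seed, "background"), {
    shaped_noise(n, shapes$background, profile$background_scale, mult = af)
  })
  x_pk <- numeric(n)
  for (i in seq_along(profile$peaks)) {
    x_pk <- x_pk + with_seed(derive_seed(seed, paste0("peak", i)), {
      shaped_noise(n, shapes$peaks[[i]], profile$peaks[[i]]$amplitude, mult = af)
    })
  }
  x <- x_bg + x_pk

  if (!is.null(modulation) && modulation$suppression_fraction > 0) {
    # split the neural signal into the suppression band and the remainder,
    # then apply the time-domain envelope to the in-band part only
    X <- stats::fft(x)
    sel1 <- freqs >= modulation$suppression_band[1] &
      freqs < modulation$suppression_band[2]
    sel2 <- onesided_to_twosided(as.numeric(sel1), n)
    x_in <- Re(stats::fft(X * sel2, inverse = TRUE)) / n
    env <- modulation_envelope(tt, paradigm, modulation)
    x <- (x - x_in) + env * x_in
  }

  r_peak_times <- numeric(0)
  if (!is.null(ecg) && ecg$qrs_amplitude > 0) {
    r_peak_times <- with_seed(derive_seed(seed, "ecg"), {
      ibi_mean <- 60 / ecg$heart_rate
      n_max <- ceiling(total / ibi_mean) + 5
      ibi <- pmax(0.3, stats::rnorm(n_max, ibi_mean, ecg$jitter_sd / 1000))
      r <- stats::runif(1, 0.2, 0.2 + ibi_mean) + cumsum(c(0, ibi))
      r[r < total - 0.3]
    })
    sg <- ecg$qrs_width / 1000 / 4
    half <- ceiling(4 * sg * rate)
    ku <- (-half:half) / rate
    kernel <- ecg$qrs_amplitude * (1 - (ku / sg)^2) * exp(-ku^2 / (2 * sg^2))
    ecg_sig <- numeric(n)
    for (r in r_peak_times) {
      c0 <- round(r * rate) + 1
      idx <- (c0 - half):(c0 + half)
      ok <- idx >= 1 & idx <= n
      ecg_sig[idx[ok]] <- ecg_sig[idx[ok]] + kernel[ok]
    }
    x <- x + ecg_sig
  }

  if (profile$line_noise_amp > 0) {
    phi <- with_seed(derive_seed(seed, "line"), stats::runif(1, 0, 2 * pi))
    x <- x + profile$line_noise_amp * sin(2 * pi * 50 * tt + phi)
  }

  list(
    ts = time_series(x, rate, t0 = 0, channel_names = "LFP", units = "uV"),
    r_peak_times = r_peak_times,
    freqs = freqs, shapes = shapes, pow_factor = pf
  )
}

#' Generate a synthetic subthalamic LFP recording
#'
#' Produces a single-channel 250 Hz series following the session paradigm:
#' a 1/f background plus stochastic narrow-band oscillatory peaks, with the
#' power inside the movement-modulation band multiplied by
#' `1 - suppression_fraction` during tapping blocks, plus optional ECG
#' contamination and 50 Hz line noise. Deterministic for a fixed seed.
#'
#' @param profile a [spectral_profile()]
#' @param modulation a [movement_modulation()] or `NULL` for none
#' @param ecg an [ecg_model()] or `NULL` for none
#' @param paradigm a [paradigm_spec()]
#' @param rate sampling rate in Hz (must exceed twice the highest peak centre)
#' @param seed integer seed
#' @param band_factors optional list of `list(band = c(lo, hi), factor = f)`
#'   multiplicative power factors (condition effects) applied to the whole
#'   neural spectrum
#' @return an `lfp_ts` with one channel
#' @export
#' @examples
#' lfp <- generate_lfp(spectral_profile(), seed = 1)
generate_lfp <- function(profile, modulation = NULL, ecg = NULL,
                         paradigm = paradigm_spec(), rate = 250, seed = 1,
                         band_factors = NULL) {
  generate_lfp_impl(profile, modulation, ecg, paradigm, rate, seed,
                    band_factors)$ts
}

#' Generate a synthetic tri-axial accelerometer trace
#'
#' Each tap is a single sinusoidal cycle of width `tap_duration` (positive
#' opening-acceleration peak followed by a negative closing peak), projected
#' onto three axes with fixed weights, plus white noise. Taps occur only
#' inside tapping blocks, `round(tap_rate * block_duration)` per block.
#'
#' @param paradigm a [paradigm_spec()]
#' @param rate sampling rate in Hz
#' @param noise_sd per-axis white-noise standard deviation (m/s^2)
#' @param seed integer seed
#' @param amplitude peak opening acceleration (m/s^2)
#' @param axis_weights length-3 projection of the tap waveform on the axes
#'   (normalised internally so the principal axis carries `amplitude`)
#' @param time_shift subtract this many seconds from all tap times (models the
#'   accelerometer clock starting `time_shift` s after the LFP clock)
#' @return an `lfp_ts` with three channels
#' @export
generate_accelerometer <- function(paradigm, rate = 4000, noise_sd = 0.3,
                                   seed = 1, amplitude = 10,
                                   axis_weights = c(0.8, 0.5, 0.33),
                                   time_shift = 0) {
  if (1 / paradigm$tap_rate < paradigm$tap_duration / 1000) {
    stop("taps would overlap: 1/tap_rate shorter than tap_duration")
  }
  total <- paradigm_duration(paradigm)
  n <- round(total * rate)
  tt <- (seq_len(n) - 1) / rate
  w <- axis_weights / max(abs(axis_weights))
  td <- paradigm$tap_duration / 1000
  pulse <- numeric(n)
  onsets <- paradigm_tap_onsets(paradigm) - time_shift
  np <- round(td * rate)
  ku <- (seq_len(np) - 1) / rate
  # biphasic "double sinusoidal" tap: a faster, stronger opening lobe
  # (peaking at 0.2 * tap_duration) followed by a slower closing lobe
  kernel <- ifelse(ku < 0.4 * td,
                   amplitude * sin(pi * ku / (0.4 * td)),
                   -0.7 * amplitude * sin(pi * (ku - 0.4 * td) / (0.6 * td)))
  for (on in onsets) {
    i0 <- round(on * rate) + 1
    idx <- i0:(i0 + np - 1)
    ok <- idx >= 1 & idx <= n
    pulse[idx[ok]] <- pulse[idx[ok]] + kernel[ok]
  }
  dat <- outer(pulse, w)
  if (noise_sd > 0) {
    dat <- dat + with_seed(derive_seed(seed, "accnoise"), {
      matrix(stats::rnorm(n * 3, 0, noise_sd), ncol = 3)
    })
  }
  time_series(dat, rate, t0 = 0, channel_names = c("ax", "ay", "az"),
              units = "m/s^2")
}

#' Default per-condition study configuration for the generator
#'
#' Collects the generator settings that define a four-condition study:
#' the rest spectral profile, condition effect map (multiplicative band-power
#' factors applied when medication and/or stimulation are on), per-condition
#' movement modulation and tap rates, ECG model, paradigm timing, stream
#' rates, clock-offset range, and hemisphere-level heterogeneity used by
#' [draw_hemisphere_config()].
#'
#' @param profile rest-state [spectral_profile()] (M0S0)
#' @param effects list with elements `med` and `stim`, each a list of
#'   `list(band, factor)` power factors applied when that therapy is on
#' @param modulation named list of [movement_modulation()] per condition label
#' @param tap_rates named numeric, taps/s per condition label
#' @param ecg an [ecg_model()] or `NULL`
#' @param paradigm base [paradigm_spec()] (its `tap_rate` is overridden per
#'   condition)
#' @param accel_noise_sd,accel_amplitude accelerometer noise and tap amplitude
#' @param offset_range range (s) from which the LFP-accelerometer clock
#'   offset is drawn uniformly
#' @param lfp_rate,accel_rate sampling rates in Hz
#' @param heterogeneity list of across-hemisphere variation parameters:
#'   `center_sd` (Hz, additive on peak centres), `amp_sdlog` and `bg_sdlog`
#'   (log-normal factors on peak amplitudes / background scale),
#'   `tap_rate_sd` (Hz, additive on all condition tap rates)
#' @return an object of class `session_config`
#' @export
session_config <- function(profile = spectral_profile(),
                           effects = list(
                             med = list(list(band = c(13, 20), factor = 0.5)),
                             stim = list(list(band = c(13, 35), factor = 0.6))
                           ),
                           modulation = list(
                             M0S0 = movement_modulation(c(18, 28), 0.5),
                             M1S0 = movement_modulation(c(8, 35), 0.5),
                             M0S1 = movement_modulation(c(5, 35), 0.5),
                             M1S1 = movement_modulation(c(5, 35), 0.5)
                           ),
                           tap_rates = c(M0S0 = 1.31, M0S1 = 2.13,
                                         M1S0 = 2.32, M1S1 = 3.17),
                           ecg = ecg_model(),
                           paradigm = paradigm_spec(),
                           accel_noise_sd = 0.3,
                           accel_amplitude = 10,
                           offset_range = c(-0.5, 0.5),
                           lfp_rate = 250, accel_rate = 4000,
                           heterogeneity = list(center_sd = 2.31,
                                                amp_sdlog = 0.2,
                                                bg_sdlog = 0.1,
                                                tap_rate_sd = 0.3)) {
  structure(list(profile = profile, effects = effects, modulation = modulation,
                 tap_rates = tap_rates, ecg = ecg, paradigm = paradigm,
                 accel_noise_sd = accel_noise_sd,
                 accel_amplitude = accel_amplitude,
                 offset_range = offset_range, lfp_rate = lfp_rate,
                 accel_rate = accel_rate, heterogeneity = heterogeneity),
            class = "session_config")
}

#' Draw a hemisphere-specific variant of a study configuration
#'
#' Applies across-hemisphere variability (peak-centre shifts, log-normal
#' amplitude and background factors, a hemisphere-level shift of all tapping
#' rates) to a base [session_config()]. The returned config is then used for
#' all four conditions of that hemisphere, preserving the paired design.
#'
#' @param config a [session_config()]
#' @param seed integer seed
#' @return a modified `session_config`
#' @export
draw_hemisphere_config <- function(config, seed) {
  het <- config$heterogeneity
  with_seed(derive_seed(seed, "hemisphere"), {
    prof <- config$profile
    for (i in seq_along(prof$peaks)) {
      shift <- stats::rnorm(1, 0, het$center_sd)
      shift <- max(min(shift, 2 * het$center_sd), -2 * het$center_sd)
      prof$peaks[[i]]$center <- max(prof$peaks[[i]]$center + shift, 3)
      prof$peaks[[i]]$amplitude <-
        prof$peaks[[i]]$amplitude * stats::rlnorm(1, 0, het$amp_sdlog)
    }
    prof$background_scale <-
      prof$background_scale * stats::rlnorm(1, 0, het$bg_sdlog)
    config$profile <- prof
    config$tap_rates <- pmax(config$tap_rates +
                               stats::rnorm(1, 0, het$tap_rate_sd), 0.5)
    config
  })
}

#' One condition's paired LFP + accelerometer recording
#'
#' @param lfp,accel `lfp_ts` streams
#' @param condition a [condition_label()]
#' @param paradigm a [paradigm_spec()]
#' @param clock_offset accelerometer start time minus LFP start time (s)
#' @return an object of class `session_recording`
#' @export
session_recording <- function(lfp, accel, condition, paradigm, clock_offset = 0) {
  stopifnot(inherits(lfp, "lfp_ts"), inherits(accel, "lfp_ts"),
            inherits(condition, "condition_label"),
            inherits(paradigm, "paradigm_spec"))
  structure(list(lfp = lfp, accel = accel, condition = condition,
                 paradigm = paradigm, clock_offset = clock_offset),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session %s> LFP %.1f s @ %g Hz | accel %.1f s @ %g Hz | clock offset %+.4f s\n",
              format(x$condition), ts_duration(x$lfp), x$lfp$rate,
              ts_duration(x$accel), x$accel$rate, x$clock_offset))
  invisible(x)
}

#' Generate a full ground-truthed session for one condition
#'
#' Applies the configuration's condition effect map (multiplicative band
#' factors for medication and stimulation), the condition's movement
#' modulation and tapping rate, draws a clock offset between the streams,
#' and records the injected ground truth.
#'
#' @param condition a [condition_label()] or label string
#' @param config a [session_config()]
#' @param seed integer seed; identical `(condition, config, seed)` give
#'   bit-identical sessions
#' @param streams which streams to synthesise: `"both"` (default) or
#'   `"lfp"` only (faster, for spectra-only studies; the accelerometer slot
#'   is a placeholder series)
#' @return a list with elements `recording` (a [session_recording()]) and
#'   `ground_truth` (injected tap times, R-peak times, true peak frequency,
#'   true band powers, clock offset)
#' @export
#' @examples
#' s <- generate_session("M0S0", seed = 1)
#' s$ground_truth$true_peak_freq
generate_session <- function(condition, config = session_config(), seed = 1,
                             streams = c("both", "lfp")) {
  streams <- match.arg(streams)
  if (is.character(condition)) condition <- condition_label(condition)
  label <- format(condition)
  if (!label %in% names(config$tap_rates)) stop("unknown condition label: ", label)

  band_factors <- list()
  if (condition$med == 1) band_factors <- c(band_factors, config$effects$med)
  if (condition$stim == 1) band_factors <- c(band_factors, config$effects$stim)
  if (length(band_factors) == 0) band_factors <- NULL

  modulation <- if (inherits(config$modulation, "movement_modulation")) {
    config$modulation
  } else {
    config$modulation[[label]]
  }

  paradigm <- config$paradigm
  paradigm$tap_rate <- unname(config$tap_rates[label])

  offset <- with_seed(derive_seed(seed, paste0("offset", label)), {
    stats::runif(1, config$offset_range[1], config$offset_range[2])
  })

  lfp_det <- generate_lfp_impl(config$profile, modulation, config$ecg,
                               paradigm, config$lfp_rate,
                               seed = derive_seed(seed, paste0("lfp", label)),
                               band_factors = band_factors)
  accel <- if (streams == "both") {
    generate_accelerometer(paradigm, config$accel_rate,
                           config$accel_noise_sd,
                           seed = derive_seed(seed, paste0("acc", label)),
                           amplitude = config$accel_amplitude,
                           time_shift = offset)
  } else {
    time_series(matrix(0, 2, 3), config$accel_rate, t0 = 0,
                channel_names = c("ax", "ay", "az"), units = "m/s^2")
  }

  # ground truth from the deterministic generation profile
  freqs <- lfp_det$freqs
  shapes <- lfp_det$shapes
  pf <- lfp_det$pow_factor
  peak_density <- rep(0, length(freqs))
  for (i in seq_along(config$profile$peaks)) {
    a <- shapes$peaks[[i]]
    tot <- sum(a^2)
    if (tot > 0) {
      peak_density <- peak_density +
        config$profile$peaks[[i]]$amplitude^2 * a^2 / tot
    }
  }
  if (!is.null(pf)) peak_density <- peak_density * pf
  sel <- freqs >= 10 & freqs <= 35
  true_peak_freq <- freqs[sel][which.max(peak_density[sel])]

  band_var <- function(lo, hi) {
    v <- component_band_variance(shapes$background, freqs, lo, hi,
                                 config$profile$background_scale, pf)
    for (i in seq_along(config$profile$peaks)) {
      v <- v + component_band_variance(shapes$peaks[[i]], freqs, lo, hi,
                                       config$profile$peaks[[i]]$amplitude, pf)
    }
    v
  }
  mv_factor <- function(lo, hi) {
    # fraction of [lo,hi) power surviving during tapping, given the
    # suppression band of this condition's modulation
    if (is.null(modulation)) return(1)
    ol <- max(0, min(hi, modulation$suppression_band[2]) -
                max(lo, modulation$suppression_band[1]))
    w <- ol / (hi - lo)
    (1 - w) + w * (1 - modulation$suppression_fraction)
  }
  true_band_power <- list(
    rest = c(low_beta = band_var(13, 20) / 7, high_beta = band_var(20, 35) / 15),
    movement = c(low_beta = band_var(13, 20) / 7 * mv_factor(13, 20),
                 high_beta = band_var(20, 35) / 15 * mv_factor(20, 35))
  )

  tap_times <- paradigm_tap_onsets(paradigm) + 0.2 * paradigm$tap_duration / 1000

  list(
    recording = session_recording(lfp_det$ts, accel, condition, paradigm,
                                  clock_offset = offset),
    ground_truth = list(
      tap_times = tap_times,
      r_peak_times = lfp_det$r_peak_times,
      true_peak_freq = true_peak_freq,
      true_band_power = true_band_power,
      clock_offset = offset,
      suppression = if (is.null(modulation)) NULL else unclass(modulation)
    )
  )
}
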
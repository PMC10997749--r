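# Shared fixtures, built in code.

# Short paradigm for fast unit tests (rest still long enough for a 30 s
# rest spectrum after wavelet edges).
quick_paradigm <- function(tap_rate = 2) {
  paradigm_spec(rest_duration = 40, n_blocks = 2, block_duration = 10,
                interblock_rest = 10, tap_rate = tap_rate)
}

sine_ts <- function(freq, dur = 30, rate = 250, amp = 1, t0 = 0) {
  tt <- seq(0, dur - 1 / rate, by = 1 / rate)
  time_series(amp * sin(2 * pi * freq * tt), rate, t0 = t0)
}

# Steady-state amplitude of a (filtered) sine, measured away from the edges.
sine_amp <- function(ts, trim = 0.2) {
  x <- ts$data[, 1]
  n <- length(x)
  i <- seq(floor(n * trim), ceiling(n * (1 - trim)))
  sqrt(2) * stats::sd(x[i])
}

# Independent band-power oracle: raw periodogram variance in [lo, hi).
oracle_band_power <- function(x, rate, lo, hi) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  pw <- (Mod(X[seq_len(floor(n / 2) + 1)])^2) / n^2
  fr <- seq(0, floor(n / 2)) * rate / n
  2 * sum(pw[fr >= lo & fr < hi])
}

# Independent smoothed-periodogram peak-frequency oracle.
oracle_peak_freq <- function(x, rate, spans = 15) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = rate), spans = spans,
                          plot = FALSE, taper = 0)
  sp$freq[which.max(sp$spec)]
}

# Independent brute-force oracle for the paired sign-flip test: enumerate
# all 2^n sign patterns of the differences.
brute_force_paired_p <- function(a, b) {
  d <- a - b
  n <- length(d)
  obs <- mean(d)
  grid <- expand.grid(rep(list(c(-1, 1)), n))
  null <- apply(grid, 1, function(s) mean(s * d))
  mean(abs(null) >= abs(obs) - 1e-12 * max(abs(d), 1))
}

# Membership of times in a set of [lo, hi] intervals.
within_any <- function(t, iv) {
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(iv))) out <- out | (t >= iv[i, 1] & t <= iv[i, 2])
  out
}

# LFP with ECG contamination plus the injected beat times.
generate_lfp_with_truth <- function(bpm, paradigm = paradigm_spec(), seed = 1) {
  cfg <- session_config(ecg = ecg_model(heart_rate = bpm), paradigm = paradigm)
  s <- generate_session("M0S0", cfg, seed = seed, streams = "lfp")
  list(ts = s$recording$lfp, r_peak_times = s$ground_truth$r_peak_times)
}

# A cheap ECG-free, line-free profile for filter-level tests.
plain_profile <- function(...) {
  spectral_profile(line_noise_amp = 0, ...)
}
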
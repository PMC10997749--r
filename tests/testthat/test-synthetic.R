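# Synthetic session generator: determinism, spectral fidelity, movement
# modulation, tap pulses, condition effects, ground-truth consistency.

test_that("generation is deterministic for a fixed (config, seed)", {
  cfg <- session_config()
  a <- generate_session("M1S1", cfg, seed = 11)
  b <- generate_session("M1S1", cfg, seed = 11)
  expect_identical(a$recording$lfp$data, b$recording$lfp$data)
  expect_identical(a$recording$accel$data, b$recording$accel$data)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- generate_session("M1S1", cfg, seed = 12)
  expect_false(identical(a$recording$lfp$data, c$recording$lfp$data))
})

test_that("all-zero amplitudes give an all-zero series", {
  p <- spectral_profile(background_scale = 0,
                        peaks = list(list(center = 17, amplitude = 0, fwhm = 4)),
                        line_noise_amp = 0)
  z <- generate_lfp(p, ecg = ecg_model(qrs_amplitude = 0), seed = 1)
  expect_true(all(z$data == 0))
  expect_equal(nrow(z$data), paradigm_duration(paradigm_spec()) * 250)
})

test_that("an injected spectral peak dominates the periodogram at its frequency", {
  p <- plain_profile(background_scale = 0.2,
                     peaks = list(list(center = 17, amplitude = 0.6, fwhm = 4)))
  for (seed in 1:5) {
    x <- generate_lfp(p, seed = seed)
    expect_lt(abs(oracle_peak_freq(x$data[, 1], 250) - 17), 1)
  }
})

test_that("movement modulation suppresses band power by the configured fraction", {
  p <- plain_profile(background_scale = 0.3,
                     peaks = list(list(center = 25, amplitude = 0.8, fwhm = 6)))
  mod <- movement_modulation(c(20, 30), suppression_fraction = 0.5,
                             rebound_fraction = 0)
  par <- paradigm_spec()
  ratios <- sapply(1:5, function(seed) {
    x <- generate_lfp(p, modulation = mod, paradigm = par, seed = seed)
    tt <- ts_times(x)
    bs <- block_spans(par)
    # interior of blocks vs interior of initial rest (avoid ramps)
    tap_sel <- within_any(tt, cbind(bs[, 1] + 0.5, bs[, 2] - 0.5))
    rest_sel <- tt > 1 & tt < par$rest_duration - 1
    oracle_band_power(x$data[tap_sel, 1], 250, 20, 30) /
      oracle_band_power(x$data[rest_sel, 1], 250, 20, 30)
  })
  expect_lt(abs(mean(ratios) - 0.5), 0.1)  # within 20% of 0.5
})

test_that("noiseless accelerometer has exactly the configured tap pulses", {
  par <- paradigm_spec(tap_rate = 2)  # 3 blocks x 10 s x 2 Hz = 60 taps
  acc <- generate_accelerometer(par, noise_sd = 0, seed = 1)
  v <- acc$data[, 1]
  n <- length(v)
  peaks <- which(diff(sign(diff(v))) == -2 & v[2:(n - 1)] > 5) + 1
  expect_identical(length(peaks), 60L)
  tt <- ts_times(acc)
  expect_true(all(v[tt < par$rest_duration] == 0))
  # typical off-therapy tapping rate: 13 pulses in each 10 s block
  par2 <- paradigm_spec(tap_rate = 1.31)
  acc2 <- generate_accelerometer(par2, noise_sd = 0, seed = 1)
  v2 <- acc2$data[, 1]
  bs <- block_spans(par2)
  tt2 <- ts_times(acc2)
  for (b in seq_len(nrow(bs))) {
    sel <- tt2 >= bs[b, 1] & tt2 <= bs[b, 2]
    vb <- v2[sel]
    nb <- sum(diff(sign(diff(vb))) == -2 & vb[2:(length(vb) - 1)] > 5)
    expect_identical(nb, 13L)
  }
})

test_that("condition effect map scales band powers by the configured factors", {
  cfg <- session_config(
    profile = plain_profile(),
    effects = list(med = list(list(band = c(13, 20), factor = 0.4)),
                   stim = list(list(band = c(20, 35), factor = 0.5))),
    ecg = ecg_model(qrs_amplitude = 0),
    modulation = NULL
  )
  ratios <- sapply(1:4, function(seed) {
    a <- generate_session("M0S0", cfg, seed = seed, streams = "lfp")
    b <- generate_session("M1S1", cfg, seed = seed, streams = "lfp")
    rest <- seq_len(55 * 250)
    c(oracle_band_power(b$recording$lfp$data[rest, 1], 250, 13, 20) /
        oracle_band_power(a$recording$lfp$data[rest, 1], 250, 13, 20),
      oracle_band_power(b$recording$lfp$data[rest, 1], 250, 20, 35) /
        oracle_band_power(a$recording$lfp$data[rest, 1], 250, 20, 35))
  })
  expect_lt(abs(mean(ratios[1, ]) - 0.4), 0.4 * 0.15)
  expect_lt(abs(mean(ratios[2, ]) - 0.5), 0.5 * 0.15)
  # ground-truth band powers reflect the same factors
  a <- generate_session("M0S0", cfg, seed = 1, streams = "lfp")
  b <- generate_session("M1S1", cfg, seed = 1, streams = "lfp")
  expect_equal(b$ground_truth$true_band_power$rest[["low_beta"]] /
                 a$ground_truth$true_band_power$rest[["low_beta"]], 0.4,
               tolerance = 0.02)
})

test_that("ground truth is internally consistent", {
  s <- generate_session("M0S0", seed = 3)
  gt <- s$ground_truth
  bs <- block_spans(s$recording$paradigm)
  expect_true(all(diff(gt$tap_times) > 0))
  expect_true(all(within_any(gt$tap_times, bs)))
  expect_true(all(diff(gt$r_peak_times) > 0.25))
  expect_true(gt$true_peak_freq >= 13 && gt$true_peak_freq <= 20)  # M0S0 low beta
  expect_equal(gt$clock_offset, s$recording$clock_offset)
})

test_that("invalid inputs are rejected", {
  expect_error(spectral_profile(peaks = list(list(center = 130, amplitude = 1, fwhm = 2))),
               "center")
  expect_error(generate_lfp(spectral_profile(
    peaks = list(list(center = 120, amplitude = 1, fwhm = 2))), rate = 200),
    "Nyquist")
  expect_error(paradigm_spec(rest_duration = -1), "durations")
  expect_error(generate_accelerometer(paradigm_spec(tap_rate = 6)), "overlap")
  expect_error(generate_session("M2S0"), "condition")
  expect_error(movement_modulation(c(20, 10)), "lo")
  expect_error(ecg_model(heart_rate = 200), "heart_rate")
})
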
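# Filters, R-peak detection and ECG template subtraction.

test_that("band-pass passes beta, kills DC/drift, corners near 5 and 90 Hz", {
  dc <- time_series(rep(1, 250 * 30), 250)
  expect_lt(max(abs(bandpass_lfp(dc)$data)), 1e-6)
  expect_equal(sine_amp(bandpass_lfp(sine_ts(20))), 1, tolerance = 0.05)
  expect_lt(sine_amp(bandpass_lfp(sine_ts(2))), 0.2)
  # -3 dB corners within 10%
  g5 <- sine_amp(bandpass_lfp(sine_ts(5, dur = 60)))
  g90 <- sine_amp(bandpass_lfp(sine_ts(90, dur = 60)))
  expect_equal(g5, 1 / sqrt(2), tolerance = 0.1)
  expect_equal(g90, 1 / sqrt(2), tolerance = 0.1)
  expect_equal(nrow(bandpass_lfp(sine_ts(20))$data), 250 * 30)
  expect_error(bandpass_lfp(time_series(rnorm(500), 100)), "rate")
})

test_that("notch removes 50 Hz, spares 20 Hz and the 45/55 Hz flanks", {
  expect_lt(sine_amp(notch_line(sine_ts(50))), 0.1)
  expect_equal(sine_amp(notch_line(sine_ts(20))), 1, tolerance = 0.02)
  expect_gt(sine_amp(notch_line(sine_ts(45, dur = 60))), 10^(-3 / 20))
  expect_gt(sine_amp(notch_line(sine_ts(55, dur = 60))), 10^(-3 / 20))
  z <- notch_line(time_series(rep(0, 5000), 250))
  expect_true(all(z$data == 0))
})

test_that("filters are linear", {
  x <- generate_lfp(plain_profile(), seed = 8)
  xs <- x
  xs$data <- xs$data * 3.7
  expect_equal(bandpass_lfp(xs)$data, 3.7 * bandpass_lfp(x)$data,
               tolerance = 1e-9)
  expect_equal(notch_line(xs)$data, 3.7 * notch_line(x)$data,
               tolerance = 1e-9)
})

test_that("R-peaks are found at the injected beat times", {
  par <- paradigm_spec(rest_duration = 60, n_blocks = 1, block_duration = 10,
                       interblock_rest = 10)
  for (bpm in c(60, 80)) {
    raw <- generate_lfp_with_truth(bpm, par, seed = bpm)
    lfp <- notch_line(bandpass_lfp(raw$ts))
    qrs <- detect_r_peaks(lfp)
    truth <- raw$r_peak_times
    expect_lt(abs(length(qrs$r_peak_times) - length(truth)), 2)
    # each detected peak within 10 ms of an injected beat
    err <- vapply(qrs$r_peak_times,
                  function(t) min(abs(truth - t)), numeric(1))
    expect_lt(stats::quantile(err, 0.95), 0.010 + 1e-9)
  }
})

test_that("absent ECG yields an empty annotation with a warning", {
  x <- generate_lfp(plain_profile(background_scale = 0.05,
                                  peaks = list(list(center = 17, amplitude = 0.02, fwhm = 4))),
                    ecg = NULL, seed = 9)
  expect_warning(qrs <- detect_r_peaks(bandpass_lfp(x)), "no plausible")
  expect_length(qrs$r_peak_times, 0)
})

test_that("template subtraction removes the artifact and spares beta power", {
  raw <- generate_lfp_with_truth(70, paradigm_spec(), seed = 21)
  lfp <- notch_line(bandpass_lfp(raw$ts))
  qrs <- detect_r_peaks(lfp)
  res <- subtract_ecg_template(lfp, qrs)
  rep <- res$report
  expect_lt(rep$artifact_power_after / rep$artifact_power_before, 0.2)
  expect_lt(abs(rep$beta_power_after - rep$beta_power_before) /
              rep$beta_power_before, 0.10)
  expect_gt(rep$n_r_peaks, 100)
  # idempotence-ish: a second pass barely changes anything
  res2 <- subtract_ecg_template(res$lfp, res$qrs)
  d1 <- sqrt(mean((res$lfp$data - lfp$data)^2))
  d2 <- sqrt(mean((res2$lfp$data - res$lfp$data)^2))
  expect_lt(d2, 0.05 * d1)
})

test_that("a single-peak annotation zeroes its own epoch", {
  x <- time_series(rnorm(250 * 10), 250)
  qrs <- qrs_annotation(5)
  res <- subtract_ecg_template(x, qrs)
  half <- round(0.2 * 250)
  c0 <- 5 * 250 + 1
  expect_true(all(res$lfp$data[(c0 - half):(c0 + half), 1] == 0))
  outside <- setdiff(seq_len(2500), (c0 - half):(c0 + half))
  expect_equal(res$lfp$data[outside, 1], x$data[outside, 1])
})

test_that("cleaning an ECG-free signal barely changes beta power", {
  x <- generate_lfp(plain_profile(), ecg = NULL, seed = 10)
  lfp <- bandpass_lfp(x)
  spurious <- qrs_annotation(seq(2, 115, by = 0.86))
  res <- subtract_ecg_template(lfp, spurious)
  rep <- res$report
  expect_lt(abs(rep$beta_power_after - rep$beta_power_before) /
              rep$beta_power_before, 0.02)
})

test_that("severity flag tracks the artifact-to-beta power ratio", {
  par <- paradigm_spec()
  strong <- generate_lfp(spectral_profile(),
                         ecg = ecg_model(qrs_amplitude = 8), paradigm = par,
                         seed = 11)
  none <- generate_lfp(spectral_profile(), ecg = NULL, paradigm = par, seed = 11)
  lfp_s <- notch_line(bandpass_lfp(strong))
  lfp_n <- notch_line(bandpass_lfp(none))
  qrs <- detect_r_peaks(lfp_s)
  expect_identical(subtract_ecg_template(lfp_s, qrs)$report$severity_flag,
                   "severe")
  expect_identical(subtract_ecg_template(lfp_n, qrs)$report$severity_flag,
                   "not present")
})
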
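# Tap detection and behavioural metrics.

prepared_accel <- function(tap_rate = 2, noise_sd = 0, seed = 1,
                           paradigm = quick_paradigm(tap_rate)) {
  acc <- generate_accelerometer(paradigm, noise_sd = noise_sd, seed = seed)
  list(accel = prepare_accelerometer(acc), paradigm = paradigm)
}

test_that("noiseless taps are recovered exactly, at the right times", {
  pa <- prepared_accel(tap_rate = 2)
  spans <- block_spans(pa$paradigm)
  ev <- detect_tap_peaks(pa$accel, spans)
  expect_identical(nrow(ev), 40L)  # 2 Hz x 10 s x 2 blocks
  truth <- stnbeta:::paradigm_tap_onsets(pa$paradigm) +
    0.2 * pa$paradigm$tap_duration / 1000
  expect_lt(max(abs(ev$open_peak_time - truth)), 1.5 / 250)
  expect_true(all(ev$open_peak_time < ev$close_peak_time))
  expect_true(all(ev$close_peak_time < ev$tap_end_time))
  expect_true(all(ev$open_peak_accel > 0))
  # exact metric recovery
  m <- compute_block_metrics(ev, spans[1, ])
  expect_identical(m$n_taps, 20L)
  expect_equal(m$tapping_frequency, 2.0)
})

test_that("an all-zero trace yields no events and flagged empty metrics", {
  par <- quick_paradigm()
  z <- time_series(matrix(0, 250 * 80, 3), 250)
  ev <- detect_tap_peaks(z, block_spans(par))
  expect_identical(nrow(ev), 0L)
  m <- compute_block_metrics(ev, block_spans(par)[1, ])
  expect_true(m$empty)
  expect_identical(m$n_taps, 0L)
  expect_equal(m$tapping_frequency, 0)
})

test_that("block metrics arithmetic follows the definitions", {
  ev <- data.frame(open_peak_time = seq(60.25, 69.75, length.out = 20),
                   open_peak_accel = rep(c(1, 2, 3), length.out = 20),
                   close_peak_time = seq(60.35, 69.85, length.out = 20),
                   tap_end_time = seq(60.45, 69.95, length.out = 20),
                   onset_time = seq(60.2, 69.7, length.out = 20), block = 1L)
  m <- compute_block_metrics(ev, c(60, 70))
  expect_identical(m$n_taps, 20L)
  expect_equal(m$tapping_frequency, 2.0)
  ev3 <- ev[1:3, ]
  ev3$open_peak_accel <- c(1, 2, 3)
  expect_equal(compute_block_metrics(ev3, c(60, 70))$mean_peak_acceleration, 2)
})

test_that("tap duration is recovered from synthetic taps and simple cases", {
  pa <- prepared_accel(tap_rate = 2)
  ev <- detect_tap_peaks(pa$accel, block_spans(pa$paradigm))
  est <- estimate_tap_duration(ev)
  expect_lt(abs(est$mean_ms - 205.4), 8)
  # single event: SD = 0
  expect_equal(estimate_tap_duration(ev[1, ])$sd_ms, 0)
  # two constructed events of widths 180 and 220 ms
  ev2 <- data.frame(open_peak_time = c(1.05, 2.05), open_peak_accel = 10,
                    close_peak_time = c(1.1, 2.1),
                    tap_end_time = c(1.18, 2.22),
                    onset_time = c(1.0, 2.0), block = 1L)
  expect_equal(estimate_tap_duration(ev2)$mean_ms, 200)
  expect_error(estimate_tap_duration(ev2[0, ]), "no tap events")
})

test_that("movement epochs merge overlaps and stay inside blocks", {
  ev <- data.frame(open_peak_time = c(60.5, 60.65), open_peak_accel = 10,
                   close_peak_time = c(60.6, 60.75),
                   tap_end_time = c(60.7, 60.85),
                   onset_time = c(60.45, 60.6), block = 1L)
  ep <- build_movement_epochs(ev, 200)
  expect_identical(nrow(ep$intervals), 1L)
  expect_equal(ep$intervals[1, 2] - ep$intervals[1, 1], 0.35)
  # 60 events of 200 ms: mask never exceeds 12 s
  ev60 <- data.frame(open_peak_time = seq(60.2, 89.8, length.out = 60),
                     open_peak_accel = 10,
                     close_peak_time = seq(60.3, 89.9, length.out = 60),
                     tap_end_time = seq(60.4, 90, length.out = 60),
                     onset_time = seq(60.1, 89.7, length.out = 60), block = 1L)
  ep60 <- build_movement_epochs(ev60, 200)
  expect_lte(sum(ep60$intervals[, 2] - ep60$intervals[, 1]), 12 + 1e-9)
  expect_identical(nrow(build_movement_epochs(ev[0, ], 200)$intervals), 0L)
  # containment in tapping blocks for real detections
  pa <- prepared_accel(tap_rate = 2)
  spans <- block_spans(pa$paradigm)
  m <- session_movement_metrics(pa$accel, pa$paradigm)
  pad <- m$tap_duration / 2000 + 0.01
  wide <- cbind(spans[, 1] - pad, spans[, 2] + pad)
  expect_true(all(within_any(m$epochs$intervals[, 1], wide)))
  expect_true(all(within_any(m$epochs$intervals[, 2], wide)))
})

test_that("measured tapping frequency increases with the generator tap rate", {
  rates <- c(1.31, 2.13, 3.17)
  meas <- vapply(rates, function(r) {
    pa <- prepared_accel(tap_rate = r, noise_sd = 0.3, seed = 2)
    m <- session_movement_metrics(pa$accel, pa$paradigm)
    m$summary$tapping_frequency
  }, numeric(1))
  expect_true(all(diff(meas) > 0))
  expect_equal(meas, c(1.3, 2.1, 3.2), tolerance = 0.05)
})

test_that("tap counts are robust to default sensor noise", {
  hits <- 0L
  n_runs <- 25L
  for (seed in seq_len(n_runs)) {
    pa <- prepared_accel(tap_rate = 2, noise_sd = 0.3, seed = seed)
    ev <- detect_tap_peaks(pa$accel, block_spans(pa$paradigm))
    if (abs(nrow(ev) - 40L) <= 1L) hits <- hits + 1L
  }
  expect_gte(hits, round(0.95 * n_runs) - 1L)
})
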
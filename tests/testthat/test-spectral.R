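# Morlet decomposition, sum rescaling, rest/movement spectra, beta peaks,
# band powers.

test_that("a pure sine concentrates wavelet power at its frequency", {
  x <- sine_ts(20, dur = 30)
  tf <- morlet_tf(x, freqs = 1:45)
  inner <- which(apply(tf$valid, 2, all))
  am <- apply(tf$power[, inner], 2, which.max)
  expect_true(all(tf$freqs[am] == 20))
  # >= 80% of total power within +/- 2 Hz
  tot <- rowMeans(tf$power[, inner])
  expect_gte(sum(tot[tf$freqs >= 18 & tf$freqs <= 22]) / sum(tot), 0.8)
  # amplitude calibration: unit sine -> power 1 at centre
  expect_equal(mean(tf$power[tf$freqs == 20, inner]), 1, tolerance = 0.02)
})

test_that("zero signal gives zero power; two tones give two maxima", {
  z <- time_series(rep(0, 250 * 20), 250)
  expect_true(all(morlet_tf(z, freqs = 5:40)$power == 0))
  tt <- seq(0, 30, by = 1 / 250)
  x <- time_series(sin(2 * pi * 15 * tt) + sin(2 * pi * 28 * tt), 250)
  tf <- morlet_tf(x, freqs = 5:40)
  sp <- rowMeans(tf$power[, apply(tf$valid, 2, all)])
  n <- length(sp)
  locmax <- which(c(FALSE, sp[2:(n - 1)] > sp[1:(n - 2)] &
                      sp[2:(n - 1)] > sp[3:n], FALSE))
  pk <- tf$freqs[locmax][order(sp[locmax], decreasing = TRUE)][1:2]
  expect_true(any(abs(pk - 15) <= 1))
  expect_true(any(abs(pk - 28) <= 1))
})

test_that("morlet output grid and edge flags follow the definitions", {
  x <- sine_ts(20, dur = 30)
  tf <- morlet_tf(x, freqs = 10:30)
  expect_equal(unique(round(diff(tf$times), 10)), 0.05)
  # half-wavelet edges: at 10 Hz, 8 cycles -> 0.4 s invalid at each end
  v10 <- tf$valid[tf$freqs == 10, ]
  expect_false(v10[1])
  expect_true(all(tf$times[v10] >= 0.4 - 1e-9))
  expect_error(morlet_tf(sine_ts(20, dur = 3), freqs = 2:30), "too short")
})

test_that("sum rescaling normalises the reference band to 1 and is scale-free", {
  x <- generate_lfp(plain_profile(), seed = 12)
  tf <- morlet_tf(x)
  tfn <- normalize_sum_rescale(tf)
  sel <- tfn$freqs >= 53 & tfn$freqs <= 90
  sums <- colSums(tfn$power[sel, ])
  expect_true(all(abs(sums - 1) < 1e-9))
  # multiplying the raw signal by any constant changes nothing
  xs <- x
  xs$data <- xs$data * 12.3
  tfs <- normalize_sum_rescale(morlet_tf(xs))
  expect_equal(tfs$power, tfn$power, tolerance = 1e-12)
})

test_that("rest spectrum averages the first movement-free 30 s", {
  x <- generate_lfp(plain_profile(), seed = 13)
  tfn <- normalize_sum_rescale(morlet_tf(x))
  r <- rest_spectrum(tfn, c(0, 60))
  expect_identical(r$n_samples_averaged, 600L)
  expect_identical(r$state, "rest")
  # constant map: spectrum equals the constant
  tfc <- tfn
  tfc$power <- matrix(2, nrow(tfc$power), ncol(tfc$power))
  expect_true(all(rest_spectrum(tfc, c(0, 60))$power == 2))
  # fully masked rest window errors
  expect_error(rest_spectrum(tfn, c(0, 60), movement_mask = cbind(0, 60)),
               "movement-free")
  # peak location matches the generator truth
  pk <- find_beta_peak(r)
  expect_lt(abs(pk$freq - 17.33), 1.5)
})

test_that("movement spectrum averages tap epochs; desynchronisation recovered", {
  # oscillatory power concentrated inside the suppressed band, so the band
  # ratio measures the generator's suppression rather than wavelet leakage
  # from an out-of-band peak
  cfg <- session_config(
    profile = plain_profile(background_scale = 0.3,
                            peaks = list(list(center = 25, amplitude = 0.8,
                                              fwhm = 6))),
    ecg = ecg_model(qrs_amplitude = 0),
    modulation = list(M0S0 = movement_modulation(c(20, 30), 0.5)),
    tap_rates = c(M0S0 = 2, M0S1 = 2, M1S0 = 2, M1S1 = 2)
  )
  s <- generate_session("M0S0", cfg, seed = 14)
  pr <- process_session(s$recording)
  sel <- pr$rest$freqs >= 20 & pr$rest$freqs < 30
  ratio <- mean(pr$movement$power[sel]) / mean(pr$rest$power[sel])
  expect_lt(abs(ratio - 0.5), 0.15)
  # single epoch equals that epoch's mean power
  tfc <- pr$tf
  tfc$power <- matrix(rep(seq_along(tfc$times), each = length(tfc$freqs)),
                      nrow = length(tfc$freqs))
  one <- movement_spectrum(tfc, cbind(65, 65.4))
  inm <- tfc$times >= 65 & tfc$times <= 65.4
  expect_equal(unique(one$power), mean(which(inm)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(movement_spectrum(tfc, matrix(numeric(0), ncol = 2)), "epochs")
  # epochs covering all valid time reproduce the rest spectrum on a constant map
  tfc$power <- matrix(3, length(tfc$freqs), length(tfc$times))
  all_ep <- cbind(0, max(tfc$times))
  expect_equal(movement_spectrum(tfc, all_ep)$power,
               rest_spectrum(tfc, c(0, 60))$power)
})

test_that("beta peak detection detrends 1/f, breaks ties low, flags no-peak", {
  freqs <- 1:90
  # flat spectrum with two equal spikes -> lower frequency wins
  p <- rep(1, 90)
  p[15] <- p[25] <- 3
  sp <- structure(list(power = p, freqs = freqs, state = "rest",
                       condition = NULL, n_samples_averaged = 600L),
                  class = "power_spectrum")
  expect_equal(find_beta_peak(sp)$freq, 15)
  # pure 1/f: no peak, warning, band minimum
  sp$power <- freqs^-1.5
  expect_warning(pk <- find_beta_peak(sp), "no clear beta peak")
  expect_true(pk$no_peak)
  expect_equal(pk$freq, 10)
})

test_that("band powers use [13,20) and [20,35] so 20 Hz is counted once", {
  freqs <- 1:90
  sp <- structure(list(power = rep(1, 90), freqs = freqs, state = "rest",
                       condition = NULL, n_samples_averaged = 600L),
                  class = "power_spectrum")
  bp <- band_power(sp)
  expect_equal(bp$low_beta, 1)
  expect_equal(bp$high_beta, 1)
  # power only at 17 Hz -> high beta 0; only at 20 Hz -> low beta 0
  sp$power <- as.numeric(freqs == 17)
  expect_equal(band_power(sp)$high_beta, 0)
  sp$power <- as.numeric(freqs == 20)
  expect_equal(band_power(sp)$low_beta, 0)
  expect_gt(band_power(sp)$high_beta, 0)
})

test_that("the whole spectral path is invariant to broadband gain", {
  s <- generate_session("M0S0", session_config(), seed = 15, streams = "lfp")
  lfp <- s$recording$lfp
  run <- function(l) {
    pre <- preprocess_lfp(l)
    tf <- normalize_sum_rescale(morlet_tf(pre$lfp))
    r <- rest_spectrum(tf, c(0, 60))
    list(spec = r$power, peak = suppressWarnings(find_beta_peak(r))$freq,
         bp = band_power(r))
  }
  a <- run(lfp)
  lfp$data <- lfp$data * 7.7
  b <- run(lfp)
  expect_equal(a$spec, b$spec, tolerance = 1e-12)
  expect_identical(a$peak, b$peak)
  expect_equal(a$bp$low_beta, b$bp$low_beta, tolerance = 1e-12)
  expect_equal(a$bp$high_beta, b$bp$high_beta, tolerance = 1e-12)
})
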
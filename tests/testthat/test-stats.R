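# Permutation tests, cluster inference, mixed models, normality test.

test_that("identical samples give zero statistic and p = 1", {
  r <- paired_permutation_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 1)
  expect_true(r$all_zero)
})

test_that("small-n permutation p equals exhaustive sign-flip enumeration", {
  cases <- list(
    list(a = c(3, 4, 6, 5), b = c(1, 2, 5, 2)),
    list(a = c(0.2, -1.5, 2.2, 0.0), b = c(0.1, -1.2, 1.0, 0.3)),
    list(a = c(5, 5, 5, 1), b = c(5, 5, 5, 2)),           # ties among flips
    list(a = rnorm(8), b = rnorm(8))                      # n = 8, 256 patterns
  )
  set.seed(42)
  for (cs in cases) {
    r <- paired_permutation_test(cs$a, cs$b)
    expect_true(r$exhaustive)
    expect_equal(r$p.value, brute_force_paired_p(cs$a, cs$b))
  }
})

test_that("a clear paired difference is detected at n = 12", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- rnorm(12, 1, 0.1)
    b <- rnorm(12, 0, 0.1)
    r <- paired_permutation_test(a, b, seed = seed)
    expect_lt(r$p.value, 0.01)
  }
})

test_that("Monte-Carlo p-values respect the never-zero floor", {
  a <- 1:13 + 100
  b <- 1:13
  r <- paired_permutation_test(a, b, n_permutations = 500, seed = 3)
  expect_false(r$exhaustive)
  expect_gte(r$p.value, 1 / 501)
  expect_error(paired_permutation_test(1, 2), "2 pairs")
  expect_error(paired_permutation_test(1:4, 1:3), "equal length")
})

test_that("identical spectra yield an empty cluster list", {
  X <- matrix(rep(1:35, each = 6) * 0.1, 6, 35, byrow = FALSE)
  r <- cluster_permutation_spectra(X, X, freqs = 1:35, n_permutations = 200)
  expect_identical(nrow(r$clusters), 0L)
})

test_that("a low-beta power difference produces a localized low-beta cluster", {
  hits <- 0L
  for (seed in 1:10) {
    d <- simulate_paired_spectra(lb_factor = 0.5, seed = seed)
    r <- cluster_permutation_spectra(d$A, d$B, freqs = d$freqs,
                                     n_permutations = 500, seed = seed)
    sig <- r$clusters[r$clusters$p_value < 0.05, , drop = FALSE]
    ov <- sig[sig$freq_lo <= 20 & sig$freq_hi >= 13, , drop = FALSE]
    if (nrow(ov) > 0 && all(ov$freq_hi <= 22)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("cluster test warns below 4 pairs and validates input", {
  d <- simulate_paired_spectra(n = 3, seed = 2)
  expect_warning(cluster_permutation_spectra(d$A, d$B, freqs = d$freqs,
                                             n_permutations = 200), "fewer than 4")
  expect_error(cluster_permutation_spectra(d$A, d$B[1:2, ], freqs = d$freqs),
               "identical dimensions")
  expect_error(cluster_permutation_spectra(d$A, d$B), "freqs")
})

test_that("cluster p-values are roughly valid under the null", {
  n_sig <- 0L
  n_rep <- 60L
  for (i in seq_len(n_rep)) {
    d <- simulate_paired_spectra(seed = 7000 + i)
    r <- cluster_permutation_spectra(d$A, d$B, freqs = d$freqs,
                                     n_permutations = 250, seed = i)
    if (nrow(r$clusters) && any(r$clusters$p_value < 0.05)) n_sig <- n_sig + 1L
  }
  # FWER should be near 0.05; generous band for a short Monte-Carlo run
  expect_lte(n_sig / n_rep, 0.15)
})

test_that("the mixed model recovers a known slope", {
  d <- simulate_lme_dataset(seed = 21)
  f <- fit_power_performance_lme(d$power, d$response, d$group)
  expect_false(f$pooled)
  expect_lt(abs(f$slope + 1.3), 3 * f$slope_se)
  expect_lt(f$slope_p, 0.001)
  expect_length(f$random_intercepts, 12)
  expect_length(predict(f), 48)
  expect_equal(unname(coef(f)), f$slope, tolerance = 1e-12)
})

test_that("zero-noise data give a perfect fitted-observed association", {
  d <- simulate_lme_dataset(noise_sd = 0, seed = 22)
  # residual variance ~ 0: lme4 emits convergence chatter but fits exactly
  f <- suppressWarnings(fit_power_performance_lme(d$power, d$response, d$group))
  expect_equal(f$spearman_rho, 1.0, tolerance = 1e-6)
})

test_that("degenerate mixed-model inputs are rejected", {
  expect_error(fit_power_performance_lme(rep(2, 8), rnorm(8), rep(1:4, 2)),
               "variance")
  expect_error(fit_power_performance_lme(exp(rnorm(8)), rnorm(8), rep(1, 8)),
               "2 groups")
  expect_error(fit_power_performance_lme(c(-1, exp(rnorm(7))), rnorm(8),
                                         rep(1:4, 2)), "positive")
})

test_that("the Lilliefors wrapper separates normal from exponential samples", {
  set.seed(31)
  norm_p <- replicate(20, lilliefors_test(rnorm(100))$p_value)
  expo_p <- replicate(20, lilliefors_test(rexp(100))$p_value)
  expect_gte(mean(norm_p > 0.05), 0.9)
  expect_gte(mean(expo_p < 0.05), 0.9)
  expect_error(lilliefors_test(c(1, 2, 3)), "at least 5")
  expect_error(lilliefors_test(rep(1, 10)), "constant")
})
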
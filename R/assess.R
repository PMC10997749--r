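# Validation suite: Monte-Carlo assessments of the pipeline's statistical
# properties on ground-truthed synthetic data. Each function runs the real
# package machinery end to end and returns measured rates/errors.

# Rest spectrum of one condition through the standard cleaning + wavelet
# path, restricted to the rest period for speed.
rest_spectrum_of_condition <- function(cond, cfg, seed,
                                       freqs = c(1:45, 53:90)) {
  s <- generate_session(cond, cfg, seed = seed, streams = "lfp")
  lfp <- ts_crop(s$recording$lfp, 0, cfg$paradigm$rest_duration + 2)
  pre <- preprocess_lfp(lfp)
  tf <- normalize_sum_rescale(morlet_tf(pre$lfp, freqs = freqs))
  list(spectrum = rest_spectrum(tf, c(0, cfg$paradigm$rest_duration)),
       ground_truth = s$ground_truth)
}

#' Type-I error of the cluster permutation test under the null
#'
#' Draws paired spectrum datasets with no true condition difference
#' (see [simulate_paired_spectra()]) and measures the fraction of datasets
#' in which any cluster reaches p < `alpha` (the family-wise false-positive
#' rate of the test).
#'
#' @param n_datasets number of null datasets
#' @param n_permutations permutations per test
#' @param n_hemispheres pairs per dataset
#' @param alpha nominal level
#' @param seed integer seed
#' @return list with `rate`, `n_datasets`
#' @export
assess_cluster_type1 <- function(n_datasets = 500, n_permutations = 500,
                                 n_hemispheres = 12, alpha = 0.05, seed = 1) {
  hits <- 0L
  for (i in seq_len(n_datasets)) {
    d <- simulate_paired_spectra(n = n_hemispheres,
                                 seed = derive_seed(seed, paste0("null", i)))
    r <- cluster_permutation_spectra(d$A, d$B, freqs = d$freqs,
                                     n_permutations = n_permutations,
                                     seed = derive_seed(seed, paste0("perm", i)))
    if (nrow(r$clusters) && any(r$clusters$p_value < alpha)) hits <- hits + 1L
  }
  list(rate = hits / n_datasets, n_datasets = n_datasets)
}

#' Recovery of injected medication and DBS effect patterns
#'
#' Simulates hemispheres under M0S0, M1S0 and M0S1 with a medication effect
#' of low-beta x `med_factor` and a stimulation effect of 13-35 Hz x
#' `stim_factor`, runs the full rest-spectrum pipeline and the cluster
#' contrasts, and measures how often (a) the medication contrast yields a
#' significant cluster overlapping 13-20 Hz without extending above 22 Hz
#' and (b) the stimulation contrast yields a significant cluster reaching at
#' least 30 Hz.
#'
#' @param n_rep replicate studies
#' @param n_hemispheres hemispheres per study
#' @param n_permutations permutations per cluster test
#' @param med_factor,stim_factor injected power factors
#' @param seed integer seed
#' @return list with `med_rate`, `dbs_rate`, `med_cluster_hi` (per-replicate
#'   upper edge of the medication cluster), `n_rep`
#' @export
assess_effect_recovery <- function(n_rep = 50, n_hemispheres = 12,
                                   n_permutations = 500, med_factor = 0.5,
                                   stim_factor = 0.6, seed = 1) {
  base <- session_config(effects = list(
    med = list(list(band = c(13, 20), factor = med_factor)),
    stim = list(list(band = c(13, 35), factor = stim_factor))
  ))
  freqs <- c(1:35, 53:90)
  med_ok <- dbs_ok <- 0L
  med_hi <- rep(NA_real_, n_rep)
  for (r in seq_len(n_rep)) {
    A <- B <- C <- matrix(0, n_hemispheres, length(freqs))
    for (h in seq_len(n_hemispheres)) {
      sh <- derive_seed(seed, paste0("rep", r, "h", h))
      hcfg <- draw_hemisphere_config(base, seed = sh)
      A[h, ] <- rest_spectrum_of_condition("M0S0", hcfg, sh, freqs)$spectrum$power
      B[h, ] <- rest_spectrum_of_condition("M1S0", hcfg,
                                           derive_seed(sh, "b"), freqs)$spectrum$power
      C[h, ] <- rest_spectrum_of_condition("M0S1", hcfg,
                                           derive_seed(sh, "c"), freqs)$spectrum$power
    }
    ct_med <- cluster_permutation_spectra(A, B, freqs = freqs,
                                          n_permutations = n_permutations,
                                          seed = derive_seed(seed, paste0("cm", r)))
    sig <- ct_med$clusters[ct_med$clusters$p_value < 0.05, , drop = FALSE]
    ov <- sig[sig$freq_lo <= 20 & sig$freq_hi >= 13, , drop = FALSE]
    if (nrow(ov)) med_hi[r] <- max(ov$freq_hi)
    if (nrow(ov) > 0 && all(ov$freq_hi <= 22)) med_ok <- med_ok + 1L
    ct_dbs <- cluster_permutation_spectra(A, C, freqs = freqs,
                                          n_permutations = n_permutations,
                                          seed = derive_seed(seed, paste0("cd", r)))
    sig2 <- ct_dbs$clusters[ct_dbs$clusters$p_value < 0.05, , drop = FALSE]
    if (nrow(sig2) && max(sig2$freq_hi) >= 30) dbs_ok <- dbs_ok + 1L
  }
  list(med_rate = med_ok / n_rep, dbs_rate = dbs_ok / n_rep,
       med_cluster_hi = med_hi, n_rep = n_rep)
}

#' Recovery of an injected rest beta peak
#'
#' Generates sessions whose rest spectrum carries a single beta peak at
#' `center` Hz (default ECG and line-noise nuisances included) and measures
#' how often [find_beta_peak()] lands within `tol` Hz of it.
#'
#' @param n_sessions number of seeded sessions
#' @param center injected peak centre (Hz)
#' @param tol recovery tolerance (Hz)
#' @param seed integer seed
#' @return list with `rate`, `mean_abs_error_hz`, `n_sessions`
#' @export
assess_peak_recovery <- function(n_sessions = 100, center = 17, tol = 1,
                                 seed = 1) {
  cfg <- session_config(
    profile = spectral_profile(
      peaks = list(list(center = center, amplitude = 0.6, fwhm = 4)))
  )
  err <- vapply(seq_len(n_sessions), function(i) {
    r <- rest_spectrum_of_condition("M0S0", cfg,
                                    derive_seed(seed, paste0("pk", i)))
    pk <- suppressWarnings(find_beta_peak(r$spectrum))
    abs(pk$freq - center)
  }, numeric(1))
  list(rate = mean(err <= tol), mean_abs_error_hz = mean(err),
       n_sessions = n_sessions)
}

#' ECG template-subtraction quality
#'
#' On contaminated sessions (default generator ECG), measures the reduction
#' of cardiac-comb power and the relative change of 13-35 Hz power caused by
#' cleaning; on ECG-free sessions, measures the beta-power change caused by
#' subtracting a template built from a spurious annotation.
#'
#' @param n_sessions sessions per arm
#' @param seed integer seed
#' @return list with `artifact_reduction`, `beta_change`,
#'   `clean_beta_change` (all averaged over sessions), `n_sessions`
#' @export
assess_ecg_cleaning <- function(n_sessions = 5, seed = 1) {
  cfg <- session_config()
  red <- bch <- cch <- numeric(n_sessions)
  for (i in seq_len(n_sessions)) {
    s <- generate_session("M0S0", cfg, derive_seed(seed, paste0("ecg", i)),
                          streams = "lfp")
    lfp <- notch_line(bandpass_lfp(s$recording$lfp))
    qrs <- detect_r_peaks(lfp)
    if (length(qrs$r_peak_times) == 0) {
      red[i] <- bch[i] <- NA_real_   # beat train not found on this draw
    } else {
      rep <- subtract_ecg_template(lfp, qrs)$report
      red[i] <- 1 - rep$artifact_power_after / rep$artifact_power_before
      bch[i] <- abs(rep$beta_power_after - rep$beta_power_before) /
        rep$beta_power_before
    }
    cfg_clean <- cfg
    cfg_clean$ecg <- NULL
    sc <- generate_session("M0S0", cfg_clean,
                           derive_seed(seed, paste0("cln", i)), streams = "lfp")
    lfpc <- notch_line(bandpass_lfp(sc$recording$lfp))
    spurious <- qrs_annotation(seq(2, ts_duration(lfpc) - 2, by = 0.857))
    repc <- subtract_ecg_template(lfpc, spurious)$report
    cch[i] <- abs(repc$beta_power_after - repc$beta_power_before) /
      repc$beta_power_before
  }
  list(artifact_reduction = mean(red, na.rm = TRUE),
       beta_change = mean(bch, na.rm = TRUE),
       clean_beta_change = mean(cch), n_sessions = n_sessions)
}

#' Behavioural metric recovery from accelerometer traces
#'
#' Noiseless traces must yield the configured tap count and tapping
#' frequency exactly; at the default sensor noise the count must stay within
#' one tap of the truth; the tap-duration estimate is compared with the
#' configured duration.
#'
#' @param n_runs noisy replicate runs
#' @param tap_rate generator taps per second
#' @param seed integer seed
#' @return list with `exact_ok` (0/1), `noisy_count_rate`,
#'   `duration_error_ms`, `n_runs`
#' @export
assess_tap_metrics <- function(n_runs = 100, tap_rate = 2, seed = 1) {
  par <- paradigm_spec(tap_rate = tap_rate)
  spans <- block_spans(par)
  n_true <- round(tap_rate * par$block_duration) * par$n_blocks
  acc0 <- prepare_accelerometer(generate_accelerometer(par, noise_sd = 0,
                                                       seed = seed))
  ev0 <- detect_tap_peaks(acc0, spans)
  m0 <- compute_block_metrics(ev0, spans[1, ])
  exact_ok <- as.integer(nrow(ev0) == n_true &&
                           m0$n_taps == round(tap_rate * par$block_duration) &&
                           isTRUE(all.equal(m0$tapping_frequency,
                                            round(tap_rate * par$block_duration) /
                                              par$block_duration)))
  hits <- 0L
  dur_err <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    acc <- prepare_accelerometer(
      generate_accelerometer(par, noise_sd = 0.3,
                             seed = derive_seed(seed, paste0("tap", i))))
    ev <- detect_tap_peaks(acc, spans)
    if (abs(nrow(ev) - n_true) <= 1) hits <- hits + 1L
    dur_err[i] <- if (nrow(ev)) {
      estimate_tap_duration(ev)$mean_ms - par$tap_duration
    } else NA_real_
  }
  list(exact_ok = exact_ok, noisy_count_rate = hits / n_runs,
       duration_error_ms = mean(abs(dur_err), na.rm = TRUE), n_runs = n_runs)
}

#' Recovery of the movement-related beta desynchronisation
#'
#' With the oscillatory power concentrated inside the suppressed band (so
#' that the band ratio measures the generator's suppression rather than
#' wavelet leakage from neighbouring peaks), computes the movement/rest
#' normalised power ratio in the suppression band.
#'
#' @param n_sessions sessions to average
#' @param suppression_band,suppression_fraction injected modulation
#' @param seed integer seed
#' @return list with `ratio` (mean over sessions), `n_sessions`
#' @export
assess_desync_recovery <- function(n_sessions = 8,
                                   suppression_band = c(20, 30),
                                   suppression_fraction = 0.5, seed = 1) {
  cfg <- session_config(
    profile = spectral_profile(
      background_scale = 0.3,
      peaks = list(list(center = mean(suppression_band), amplitude = 0.8,
                        fwhm = 6)),
      line_noise_amp = 0),
    ecg = ecg_model(qrs_amplitude = 0),
    modulation = list(M0S0 = movement_modulation(suppression_band,
                                                 suppression_fraction)),
    tap_rates = c(M0S0 = 2, M0S1 = 2, M1S0 = 2, M1S1 = 2)
  )
  ratios <- vapply(seq_len(n_sessions), function(i) {
    s <- generate_session("M0S0", cfg, derive_seed(seed, paste0("ds", i)))
    pr <- process_session(s$recording)
    sel <- pr$rest$freqs >= suppression_band[1] &
      pr$rest$freqs < suppression_band[2]
    mean(pr$movement$power[sel]) / mean(pr$rest$power[sel])
  }, numeric(1))
  list(ratio = mean(ratios), n_sessions = n_sessions)
}

#' Coverage of the mixed-model slope estimator
#'
#' Simulates grouped power-performance datasets with a known slope (see
#' [simulate_lme_dataset()]) and measures how often the 95% confidence
#' interval of the fitted slope covers the truth, plus the Spearman
#' correlation between fitted and observed responses in the zero-noise case.
#'
#' @param n_rep replicates
#' @param slope true slope
#' @param noise_sd residual SD
#' @param seed integer seed
#' @return list with `coverage`, `mean_slope`, `zero_noise_rho`, `n_rep`
#' @export
assess_lme_recovery <- function(n_rep = 200, slope = -1.3, noise_sd = 0.3,
                                seed = 1) {
  cover <- 0L
  slopes <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    d <- simulate_lme_dataset(slope = slope, noise_sd = noise_sd,
                              seed = derive_seed(seed, paste0("lme", i)))
    f <- suppressWarnings(fit_power_performance_lme(d$power, d$response,
                                                    d$group))
    slopes[i] <- f$slope
    # Satterthwaite-df t interval
    ci <- f$slope + c(-1, 1) * stats::qt(0.975, f$slope_df) * f$slope_se
    if (ci[1] <= slope && slope <= ci[2]) cover <- cover + 1L
  }
  dz <- simulate_lme_dataset(slope = slope, noise_sd = 0,
                             seed = derive_seed(seed, "lmez"))
  fz <- suppressWarnings(fit_power_performance_lme(dz$power, dz$response,
                                                   dz$group))
  list(coverage = cover / n_rep, mean_slope = mean(slopes),
       zero_noise_rho = fz$spearman_rho, n_rep = n_rep)
}

#' Invariance of normalised spectra to broadband gain
#'
#' Runs the full preprocessing + wavelet + sum-rescaling path on a session
#' and on the same session scaled by a constant, and returns the largest
#' absolute difference across the normalised rest spectrum, the beta peak
#' frequency and the canonical band powers.
#'
#' @param gain multiplicative constant applied to the raw LFP
#' @param seed integer seed
#' @return list with `max_abs_diff`, `peak_diff_hz`
#' @export
assess_normalization_invariance <- function(gain = 7.7, seed = 1) {
  s <- generate_session("M0S0", session_config(), seed = derive_seed(seed, "ni"),
                        streams = "lfp")
  run <- function(lfp) {
    pre <- preprocess_lfp(lfp)
    tf <- normalize_sum_rescale(morlet_tf(pre$lfp))
    r <- rest_spectrum(tf, c(0, 60))
    bp <- band_power(r)
    list(spec = r$power, peak = suppressWarnings(find_beta_peak(r))$freq,
         bp = c(bp$low_beta, bp$high_beta))
  }
  a <- run(s$recording$lfp)
  scaled <- s$recording$lfp
  scaled$data <- scaled$data * gain
  b <- run(scaled)
  list(max_abs_diff = max(abs(a$spec - b$spec), abs(a$bp - b$bp)),
       peak_diff_hz = abs(a$peak - b$peak))
}
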
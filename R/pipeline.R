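# End-to-end four-condition study: simulate/read -> preprocess -> sync ->
# behavioural metrics -> spectra -> statistics -> report.

CONDITIONS <- c("M0S0", "M0S1", "M1S0", "M1S1")
CONTRAST_PAIRS <- list(c("M0S0", "M1S0"), c("M0S0", "M0S1"), c("M1S0", "M0S1"),
                       c("M1S0", "M1S1"), c("M0S1", "M1S1"), c("M0S0", "M1S1"))

#' Study-level configuration
#'
#' @param session a [session_config()] describing the generator conditions
#' @param n_hemispheres number of simulated hemispheres (pairing units)
#' @param seed master integer seed; every random stage derives its stream
#'   from it
#' @param n_permutations permutations for all resampling tests
#' @param cluster_alpha cluster-forming per-bin alpha
#' @param freq_range frequency range for cluster tests (Hz)
#' @param ecg_clean ECG cleaning policy, see [preprocess_lfp()]
#' @param rest_duration seconds of movement-free rest averaged per condition
#' @return an object of class `study_config`
#' @export
study_config <- function(session = session_config(), n_hemispheres = 12,
                         seed = 1, n_permutations = 2000, cluster_alpha = 0.05,
                         freq_range = c(1, 35), ecg_clean = "auto",
                         rest_duration = 30) {
  structure(list(session = session, n_hemispheres = n_hemispheres, seed = seed,
                 n_permutations = n_permutations, cluster_alpha = cluster_alpha,
                 freq_range = freq_range, ecg_clean = ecg_clean,
                 rest_duration = rest_duration),
            class = "study_config")
}

#' Process one session end to end
#'
#' Aligns the streams, prepares the accelerometer, cleans the LFP, computes
#' behavioural metrics, the normalised time-frequency map, rest and movement
#' spectra, the rest beta peak and canonical band powers.
#'
#' @param session a [session_recording()]
#' @param ecg_clean ECG cleaning policy, see [preprocess_lfp()]
#' @param rest_duration seconds of rest averaged
#' @return list with `metrics`, `rest`, `movement`, `peak`, `band_power_rest`,
#'   `band_power_movement`, `cleaning`, `tf`
#' @export
process_session <- function(session, ecg_clean = "auto", rest_duration = 30) {
  stopifnot(inherits(session, "session_recording"))
  aligned <- align_streams(session)
  accel <- prepare_accelerometer(aligned$accel)
  pre <- preprocess_lfp(aligned$lfp, ecg_clean)
  metrics <- session_movement_metrics(accel, aligned$paradigm)
  tf <- normalize_sum_rescale(morlet_tf(pre$lfp))
  rest <- rest_spectrum(tf, c(pre$lfp$t0, aligned$paradigm$rest_duration),
                        duration = rest_duration)
  rest$condition <- aligned$condition
  mov <- movement_spectrum(tf, metrics$epochs)
  mov$condition <- aligned$condition
  peak <- suppressWarnings(find_beta_peak(rest))
  list(metrics = metrics, rest = rest, movement = mov, peak = peak,
       band_power_rest = band_power(rest),
       band_power_movement = band_power(mov),
       cleaning = pre$report, tf = tf)
}

#' Run the full four-condition study
#'
#' Simulates `n_hemispheres` hemispheres (each with its own drawn spectral
#' profile and behavioural level, shared across the four conditions to
#' preserve the paired design), processes every session, and computes: the
#' behavioural metrics table; per-condition rest and movement spectra; the
#' rest beta-peak table; the six pairwise behavioural permutation tests;
#' cluster-based permutation contrasts for all six condition pairs in both
#' rest and movement; rest-vs-movement cluster contrasts per condition; and
#' four mixed-effects fits (low/high beta x rest/movement) predicting
#' tapping frequency. Fully reproducible from `(config, seed)`.
#'
#' @param config a [study_config()]
#' @return an object of class `study_report`
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  H <- config$n_hemispheres
  seed <- config$seed

  rest_sp <- stats::setNames(vector("list", 4), CONDITIONS)
  mov_sp <- stats::setNames(vector("list", 4), CONDITIONS)
  metrics <- list(); peaks <- list(); bps <- list(); cleaning <- list()
  freqs <- NULL

  for (h in seq_len(H)) {
    hcfg <- draw_hemisphere_config(config$session, derive_seed(seed, paste0("hemi", h)))
    for (cond in CONDITIONS) {
      gs <- generate_session(cond, hcfg, seed = derive_seed(seed, paste0("s", h, cond)))
      pr <- process_session(gs$recording, config$ecg_clean, config$rest_duration)
      freqs <- pr$rest$freqs
      rest_sp[[cond]] <- rbind(rest_sp[[cond]], pr$rest$power)
      mov_sp[[cond]] <- rbind(mov_sp[[cond]], pr$movement$power)
      metrics[[length(metrics) + 1]] <- cbind(
        hemisphere = h, condition = cond, pr$metrics$summary,
        tap_duration_ms = pr$metrics$tap_duration
      )
      peaks[[length(peaks) + 1]] <- data.frame(
        hemisphere = h, condition = cond, peak_freq = pr$peak$freq,
        no_peak = pr$peak$no_peak
      )
      bps[[length(bps) + 1]] <- data.frame(
        hemisphere = h, condition = cond,
        state = c("rest", "movement"),
        low_beta = c(pr$band_power_rest$low_beta, pr$band_power_movement$low_beta),
        high_beta = c(pr$band_power_rest$high_beta, pr$band_power_movement$high_beta)
      )
      cleaning[[length(cleaning) + 1]] <- data.frame(
        hemisphere = h, condition = cond,
        severity = if (is.null(pr$cleaning)) NA_character_ else pr$cleaning$severity_flag
      )
    }
  }
  metrics <- do.call(rbind, metrics)
  peaks <- do.call(rbind, peaks)
  band_powers <- do.call(rbind, bps)
  cleaning <- do.call(rbind, cleaning)

  # six pairwise behavioural contrasts (tapping frequency)
  tfreq <- function(cond) metrics$tapping_frequency[metrics$condition == cond]
  behavior <- do.call(rbind, lapply(CONTRAST_PAIRS, function(pr2) {
    tst <- paired_permutation_test(tfreq(pr2[1]), tfreq(pr2[2]),
                                   n_permutations = config$n_permutations,
                                   seed = derive_seed(seed, paste0("beh", pr2[1], pr2[2])))
    data.frame(a = pr2[1], b = pr2[2], mean_difference = unname(tst$statistic),
               p_value = tst$p.value)
  }))

  # cluster contrasts between conditions, per state
  cluster_tests <- list(rest = list(), movement = list())
  for (state in c("rest", "movement")) {
    sp <- if (state == "rest") rest_sp else mov_sp
    for (pr2 in CONTRAST_PAIRS) {
      key <- paste(pr2, collapse = ":")
      cluster_tests[[state]][[key]] <- cluster_permutation_spectra(
        sp[[pr2[1]]], sp[[pr2[2]]], freqs = freqs,
        freq_range = config$freq_range, cluster_alpha = config$cluster_alpha,
        n_permutations = config$n_permutations,
        seed = derive_seed(seed, paste0("cl", state, key))
      )
    }
  }
  # rest vs movement within condition (movement-related desynchronisation)
  desync <- list()
  for (cond in CONDITIONS) {
    desync[[cond]] <- cluster_permutation_spectra(
      rest_sp[[cond]], mov_sp[[cond]], freqs = freqs,
      freq_range = config$freq_range, cluster_alpha = config$cluster_alpha,
      n_permutations = config$n_permutations,
      seed = derive_seed(seed, paste0("ds", cond))
    )
  }

  # mixed-effects prediction of tapping frequency from beta power
  lme_fits <- list()
  for (state in c("rest", "movement")) {
    for (band in c("low_beta", "high_beta")) {
      sub <- band_powers[band_powers$state == state, ]
      sub <- sub[order(sub$hemisphere, sub$condition), ]
      met <- metrics[order(metrics$hemisphere, metrics$condition), ]
      lme_fits[[paste(band, state, sep = "_")]] <- fit_power_performance_lme(
        sub[[band]], met$tapping_frequency, sub$hemisphere
      )
    }
  }

  cfg_hash <- {
    tf_ <- tempfile()
    writeLines(deparse(config), tf_)
    h <- unname(tools::md5sum(tf_))
    unlink(tf_)
    h
  }
  structure(list(
    freqs = freqs,
    spectra = list(rest = rest_sp, movement = mov_sp),
    metrics = metrics, peaks = peaks, band_powers = band_powers,
    behavior_tests = behavior, cluster_tests = cluster_tests,
    desync_tests = desync, lme = lme_fits, cleaning = cleaning,
    provenance = list(seed = seed, config_hash = cfg_hash,
                      n_hemispheres = H,
                      package_version = as.character(utils::packageVersion("stnbeta")))
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study report> %d hemispheres x 4 conditions (seed %d, config %s)\n",
              x$provenance$n_hemispheres, x$provenance$seed,
              substr(x$provenance$config_hash, 1, 8)))
  agg <- stats::aggregate(tapping_frequency ~ condition, x$metrics, mean)
  cat("  mean tapping frequency (Hz): ",
      paste(sprintf("%s %.2f", agg$condition, agg$tapping_frequency),
            collapse = ", "), "\n")
  pk <- stats::aggregate(peak_freq ~ condition, x$peaks, mean)
  cat("  mean rest beta peak (Hz):    ",
      paste(sprintf("%s %.2f", pk$condition, pk$peak_freq), collapse = ", "), "\n")
  cat("  rest cluster contrasts:\n")
  for (key in names(x$cluster_tests$rest)) {
    ct <- x$cluster_tests$rest[[key]]
    sig <- ct$clusters[ct$clusters$p_value < 0.05, , drop = FALSE]
    cat(sprintf("    %s: %s\n", key, if (nrow(sig) == 0) "no significant cluster"
                else paste(sprintf("%g-%g Hz (p=%.3g)", sig$freq_lo, sig$freq_hi,
                                   sig$p_value), collapse = "; ")))
  }
  cat("  LME fits (predictor -> tapping frequency):\n")
  for (nm in names(x$lme)) {
    f <- x$lme[[nm]]
    cat(sprintf("    %s: slope %.3f (p=%.3g), BIC %.2f, rho %.2f\n",
                nm, f$slope, f$slope_p, f$bic, f$spearman_rho))
  }
  invisible(x)
}

#' Write the study report to disk
#'
#' Emits `report.json` (tables, cluster summaries, mixed-model summaries and
#' provenance), `spectra.csv` (tidy: hemisphere, condition, state, freq_hz,
#' power) and `metrics.csv`.
#'
#' @param report a [run_study()] report
#' @param path output directory
#' @return `path`, invisibly
#' @export
write_study_report <- function(report, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cl_sum <- function(tests) {
    lapply(tests, function(ct) ct$clusters)
  }
  lme_sum <- lapply(report$lme, function(f) {
    list(slope = f$slope, slope_p = f$slope_p, bic = f$bic,
         spearman_rho = f$spearman_rho, pooled = f$pooled)
  })
  jsonlite::write_json(
    list(metrics = report$metrics, peaks = report$peaks,
         band_powers = report$band_powers, behavior_tests = report$behavior_tests,
         cluster_tests = lapply(report$cluster_tests, cl_sum),
         desync_tests = cl_sum(report$desync_tests),
         lme = lme_sum, cleaning = report$cleaning,
         provenance = report$provenance),
    file.path(path, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows"
  )
  rows <- list()
  for (state in names(report$spectra)) {
    for (cond in names(report$spectra[[state]])) {
      m <- report$spectra[[state]][[cond]]
      rows[[length(rows) + 1]] <- data.table::data.table(
        hemisphere = rep(seq_len(nrow(m)), each = ncol(m)),
        condition = cond, state = state,
        freq_hz = rep(report$freqs, nrow(m)),
        power = as.vector(t(m))
      )
    }
  }
  data.table::fwrite(data.table::rbindlist(rows), file.path(path, "spectra.csv"))
  data.table::fwrite(report$metrics, file.path(path, "metrics.csv"))
  invisible(path)
}

#' Figures for a study report
#'
#' Writes per-state averaged-spectra overlays (with significant-cluster
#' underlays) and a behavioural box plot. Purely presentational.
#'
#' @param report a [run_study()] report
#' @param path output directory
#' @param width,height device size in pixels
#' @return character vector of files written
#' @export
make_figures <- function(report, path, width = 900, height = 600) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  cols <- c(M0S0 = "grey25", M0S1 = "goldenrod3", M1S0 = "steelblue4",
            M1S1 = "purple3")
  for (state in c("rest", "movement")) {
    sp <- report$spectra[[state]]
    if (is.null(sp) || any(vapply(sp, is.null, logical(1)))) {
      warning("report has no ", state, " spectra; skipping figure")
      next
    }
    f <- file.path(path, paste0("spectra_", state, ".png"))
    grDevices::png(f, width, height)
    means <- lapply(sp, colMeans)
    sel <- report$freqs <= 45
    graphics::matplot(report$freqs[sel],
                      do.call(cbind, lapply(means, function(m) m[sel])),
                      type = "l", lty = 1, lwd = 2, col = cols,
                      xlab = "frequency (Hz)", ylab = "normalized power",
                      main = paste("Averaged", state, "spectra"), log = "y")
    y0 <- min(vapply(means, function(m) min(m[sel]), numeric(1)))
    off <- 1
    for (key in names(report$cluster_tests[[state]])) {
      ct <- report$cluster_tests[[state]][[key]]
      sig <- ct$clusters[ct$clusters$p_value < 0.05, , drop = FALSE]
      if (nrow(sig)) {
        graphics::segments(sig$freq_lo, y0 * 1.05^off, sig$freq_hi,
                           y0 * 1.05^off, lwd = 3, col = "grey60")
        off <- off + 1
      }
    }
    graphics::legend("topright", legend = names(means), col = cols,
                     lty = 1, lwd = 2, bty = "n")
    grDevices::dev.off()
    files <- c(files, f)
  }
  f <- file.path(path, "metrics.png")
  grDevices::png(f, width, height)
  graphics::boxplot(tapping_frequency ~ condition, data = report$metrics,
                    ylab = "tapping frequency (Hz)", xlab = "",
                    main = "Motor performance by condition", col = cols)
  grDevices::dev.off()
  c(files, f)
}
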
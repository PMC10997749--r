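# Spectrum- and regression-level simulators used to validate the resampling
# and mixed-model machinery (null calibration, effect recovery, parameter
# recovery) without running the full waveform pipeline.

#' Simulate paired per-hemisphere spectra with an optional band effect
#'
#' Each pairing unit (hemisphere) gets a smooth 1/f-plus-beta-peak base
#' spectrum (peak centre jittered across hemispheres); two conditions are
#' drawn as the base times smooth multiplicative log-normal noise, with the
#' second condition's low/high beta power multiplied by `lb_factor` /
#' `hb_factor`. With both factors at 1 the two conditions are exchangeable
#' draws from the same distribution (a null dataset for calibrating the
#' cluster test).
#'
#' @param n number of hemispheres
#' @param freqs frequency grid (Hz)
#' @param lb_factor,hb_factor power factors applied to 13-20 / 20-35 Hz of
#'   the second condition
#' @param noise_sd log-scale noise SD per bin (smoothed over 3 bins, so
#'   neighbouring bins are dependent, as in wavelet spectra)
#' @param seed integer seed
#' @return list with matrices `A`, `B` (n x length(freqs)) and `freqs`
#' @export
simulate_paired_spectra <- function(n = 12, freqs = 1:35, lb_factor = 1,
                                    hb_factor = 1, noise_sd = 0.08,
                                    seed = 1) {
  with_seed(derive_seed(seed, "pairspec"), {
    draw <- function(base, fac) {
      eps <- stats::filter(stats::rnorm(length(freqs), 0, noise_sd),
                           rep(1 / sqrt(3), 3), circular = TRUE)
      base * fac * exp(as.numeric(eps))
    }
    A <- B <- matrix(0, n, length(freqs))
    for (i in seq_len(n)) {
      c0 <- stats::rnorm(1, 17.3, 1.5)
      base <- 2 * freqs^-1.2 + 1.2 * exp(-(freqs - c0)^2 / 8)
      fac <- rep(1, length(freqs))
      fac[freqs >= 13 & freqs < 20] <- lb_factor
      fac[freqs >= 20 & freqs <= 35] <- hb_factor
      A[i, ] <- draw(base, 1)
      B[i, ] <- draw(base, fac)
    }
    list(A = A, B = B, freqs = freqs)
  })
}

#' Simulate grouped power-performance data with a known slope
#'
#' Generates the design used to validate [fit_power_performance_lme()]:
#' `n_group` hemispheres with `n_cond` observations each, random intercepts
#' N(3, 0.5), log-normal beta power, response
#' `intercept + slope * log(power) + N(0, noise_sd)`.
#'
#' @param slope true fixed slope on log power
#' @param noise_sd residual SD
#' @param n_group,n_cond groups and observations per group
#' @param seed integer seed
#' @return data.frame with `power`, `response`, `group`
#' @export
simulate_lme_dataset <- function(slope = -1.3, noise_sd = 0.3, n_group = 12,
                                 n_cond = 4, seed = 1) {
  with_seed(derive_seed(seed, "lmesim"), {
    g <- rep(seq_len(n_group), each = n_cond)
    intercept <- rep(stats::rnorm(n_group, 3, 0.5), each = n_cond)
    power <- exp(stats::rnorm(n_group * n_cond, -0.5, 0.6))
    y <- intercept + slope * log(power) +
      stats::rnorm(length(g), 0, noise_sd)
    data.frame(power = power, response = y, group = g)
  })
}
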
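# Paired sign-flip permutation tests, cluster-based inference over
# frequency, and mixed-effects prediction of motor performance.

#' Two-sided paired permutation test
#'
#' Statistic: mean paired difference `mean(a - b)`. The null distribution is
#' built by random sign flips of the within-pair differences (the pairing
#' unit, e.g. a hemisphere, is the exchangeability unit). When `2^n` does not
#' exceed `n_permutations` all sign patterns are enumerated and the p-value
#' is exact; otherwise the Monte-Carlo p-value uses the +1 convention
#' `(1 + #(|null| >= |obs|)) / (n_permutations + 1)` so it is never zero.
#'
#' @param a,b paired samples (equal length >= 2)
#' @param n_permutations number of random permutations (>= 100)
#' @param seed integer seed for the random case
#' @return an object of classes `perm_test` and `htest` with `statistic`
#'   (mean difference), `p.value`, `n_permutations`, `exhaustive`,
#'   `all_zero` flag
#' @export
#' @examples
#' paired_permutation_test(c(3, 4, 6, 5), c(1, 2, 5, 2))
paired_permutation_test <- function(a, b, n_permutations = 10000, seed = 1) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  d <- a - b
  obs <- mean(d)
  all_zero <- all(d == 0)
  tol <- 1e-12 * max(abs(d), 1)
  if (all_zero) {
    p <- 1
    exhaustive <- TRUE
  } else if (2^n <= n_permutations) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null <- as.numeric(signs %*% d) / n
    p <- mean(abs(null) >= abs(obs) - tol)
    exhaustive <- TRUE
  } else {
    null <- with_seed(derive_seed(seed, "pairperm"), {
      signs <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                      n_permutations, n)
      as.numeric(signs %*% d) / n
    })
    p <- (1 + sum(abs(null) >= abs(obs) - tol)) / (n_permutations + 1)
    exhaustive <- FALSE
  }
  structure(
    list(statistic = c("mean difference" = obs), p.value = p,
         method = paste0("Two-sided paired sign-flip permutation test",
                         if (exhaustive) " (exhaustive)"),
         data.name = deparse(substitute(a)),
         n_permutations = n_permutations, exhaustive = exhaustive,
         all_zero = all_zero, n = n, seed = seed),
    class = c("perm_test", "htest")
  )
}

# Per-bin paired t statistics for a difference matrix (pairs x bins) under a
# set of sign-flip patterns (matrix n_perm x pairs). Uses the fact that the
# sum of squares of signed differences is flip-invariant.
sign_flip_t <- function(d, signs) {
  n <- nrow(d)
  ss <- colSums(d^2)
  m <- (signs %*% d) / n
  se <- sqrt(sweep(-(m^2) * n, 2, ss, "+") / (n - 1) / n)
  t <- m / se
  t[!is.finite(t)] <- 0
  t
}

# Contiguous supra-threshold runs and their |t| masses.
find_clusters <- function(tvals, crit) {
  supra <- abs(tvals) > crit
  if (!any(supra)) return(NULL)
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep],
             mass = vapply(keep, function(k) {
               sum(abs(tvals[starts[k]:ends[k]]))
             }, numeric(1)))
}

#' Cluster-based paired permutation test across frequency
#'
#' Tests paired spectra (e.g. per-hemisphere rest spectra under two
#' conditions) for frequency clusters of power differences, respecting the
#' strong dependence of neighbouring frequency bins. Per-bin paired t
#' statistics are thresholded at the two-sided `cluster_alpha` critical value
#' (df = n - 1); contiguous supra-threshold bins form clusters whose mass is
#' the summed |t|; the null distribution of the maximal cluster mass is built
#' by random sign flips of the within-pair spectral differences.
#'
#' @param spec_a,spec_b matrices (pairs x frequencies) of paired spectra, or
#'   lists of `power_spectrum` objects on a common grid
#' @param freqs frequency grid (Hz); taken from the spectra when lists are
#'   given
#' @param freq_range restrict testing to this range (default 1-35 Hz)
#' @param cluster_alpha two-sided per-bin cluster-forming alpha
#' @param n_permutations number of sign-flip permutations
#' @param seed integer seed
#' @return an object of class `cluster_perm_test`: data.frame `clusters`
#'   (`freq_lo`, `freq_hi`, `mass`, `p_value`), `tvals`, `threshold_stat`,
#'   `freqs`, `n_permutations`, `seed`
#' @export
cluster_permutation_spectra <- function(spec_a, spec_b, freqs = NULL,
                                        freq_range = c(1, 35),
                                        cluster_alpha = 0.05,
                                        n_permutations = 2000, seed = 1) {
  as_mat <- function(s) {
    if (is.list(s) && inherits(s[[1]], "power_spectrum")) {
      do.call(rbind, lapply(s, function(x) x$power))
    } else as.matrix(s)
  }
  if (is.list(spec_a) && inherits(spec_a[[1]], "power_spectrum") && is.null(freqs)) {
    freqs <- spec_a[[1]]$freqs
  }
  A <- as_mat(spec_a); B <- as_mat(spec_b)
  if (!all(dim(A) == dim(B))) stop("paired spectra must have identical dimensions")
  if (is.null(freqs)) stop("freqs must be supplied with matrix input")
  if (ncol(A) != length(freqs)) stop("spectra and frequency grid disagree")
  n <- nrow(A)
  if (n < 2) stop("need at least 2 pairs")
  if (n < 4) warning("fewer than 4 pairs; permutation null is very coarse")
  sel <- freqs >= freq_range[1] & freqs <= freq_range[2]
  d <- (A - B)[, sel, drop = FALSE]
  fr <- freqs[sel]
  crit <- stats::qt(1 - cluster_alpha / 2, df = n - 1)

  t_obs <- as.numeric(sign_flip_t(d, matrix(1, 1, n)))
  cl <- find_clusters(t_obs, crit)

  null_max <- with_seed(derive_seed(seed, "clusterperm"), {
    signs <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                    n_permutations, n)
    tperm <- sign_flip_t(d, signs)
    apply(tperm, 1, function(tv) {
      cc <- find_clusters(tv, crit)
      if (is.null(cc)) 0 else max(cc$mass)
    })
  })

  clusters <- if (is.null(cl)) {
    data.frame(freq_lo = numeric(0), freq_hi = numeric(0),
               mass = numeric(0), p_value = numeric(0))
  } else {
    data.frame(
      freq_lo = fr[cl$start], freq_hi = fr[cl$end], mass = cl$mass,
      p_value = vapply(cl$mass, function(m) {
        (1 + sum(null_max >= m)) / (n_permutations + 1)
      }, numeric(1))
    )
  }
  structure(list(clusters = clusters, tvals = t_obs, freqs = fr,
                 threshold_stat = crit, n_permutations = n_permutations,
                 n = n, seed = seed),
            class = "cluster_perm_test")
}

#' @export
print.cluster_perm_test <- function(x, ...) {
  cat(sprintf("<cluster permutation test> %d pairs, |t| > %.3f, %d permutations\n",
              x$n, x$threshold_stat, x$n_permutations))
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters))) {
      cat(sprintf("  cluster %g-%g Hz: mass %.2f, p = %.4g\n",
                  x$clusters$freq_lo[i], x$clusters$freq_hi[i],
                  x$clusters$mass[i], x$clusters$p_value[i]))
    }
  }
  invisible(x)
}

#' Mixed-effects prediction of motor performance from beta power
#'
#' Fits `response ~ log(power) + (1 | group)`: a random intercept per
#' grouping unit (hemisphere) and a single fixed slope on log-transformed
#' normalised beta power (beta power is log-scaled because it is not
#' normally distributed). Reports the slope, its p-value (Satterthwaite),
#' BIC, and the Spearman correlation between fitted and observed responses.
#' Falls back to a pooled linear regression (with a warning) if the
#' mixed-model fit fails.
#'
#' @param power positive per-observation beta power values
#' @param response per-observation motor performance (tapping frequency, Hz)
#' @param group grouping factor (hemisphere id)
#' @param log_transform log the predictor first (default TRUE)
#' @return an object of class `beta_lme`: `slope`, `slope_p`, `slope_se`,
#'   `slope_df` (Satterthwaite), `bic`, `random_intercepts`, `predicted`,
#'   `spearman_rho`, `model`
#' @export
fit_power_performance_lme <- function(power, response, group,
                                      log_transform = TRUE) {
  if (any(power <= 0) && log_transform) stop("power must be positive")
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (min(table(group)) < 2) stop("need at least 2 observations per group")
  x <- if (log_transform) log(power) else power
  if (stats::sd(x) == 0) stop("predictor has no variance; slope undefined")
  dat <- data.frame(y = response, x = x, g = group)
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(y ~ x + (1 | g), data = dat,
                                    control = lme4::lmerControl(
                                      check.conv.singular = "ignore"))),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warning("mixed-model fit failed; falling back to pooled regression")
    lmfit <- stats::lm(y ~ x, data = dat)
    co <- summary(lmfit)$coefficients
    pred <- stats::fitted(lmfit)
    out <- list(slope = co["x", "Estimate"], slope_p = co["x", "Pr(>|t|)"],
                slope_se = co["x", "Std. Error"],
                slope_df = stats::df.residual(lmfit),
                bic = stats::BIC(lmfit), random_intercepts = NULL,
                predicted = pred,
                spearman_rho = stats::cor(pred, response, method = "spearman"),
                pooled = TRUE, model = lmfit)
  } else {
    co <- stats::coef(summary(fit))
    pred <- stats::fitted(fit)
    out <- list(slope = co["x", "Estimate"], slope_p = co["x", "Pr(>|t|)"],
                slope_se = co["x", "Std. Error"],
                slope_df = co["x", "df"],
                bic = stats::BIC(fit),
                random_intercepts = lme4::ranef(fit)$g[, 1],
                predicted = pred,
                spearman_rho = stats::cor(pred, response, method = "spearman"),
                pooled = FALSE, model = fit)
  }
  class(out) <- "beta_lme"
  out
}

#' @export
print.beta_lme <- function(x, ...) {
  cat(sprintf("<beta power LME>%s slope (CoE) = %.4f (p = %.3g), BIC = %.2f, Spearman rho = %.3f\n",
              if (x$pooled) " [pooled fallback]" else "",
              x$slope, x$slope_p, x$bic, x$spearman_rho))
  invisible(x)
}

#' @export
coef.beta_lme <- function(object, ...) {
  c(slope = object$slope)
}

#' @export
predict.beta_lme <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$predicted)
  stats::predict(object$model, newdata = newdata, ...)
}

#' @export
summary.beta_lme <- function(object, ...) summary(object$model, ...)

#' Lilliefors normality test
#'
#' Kolmogorov-Smirnov test against a normal distribution with estimated mean
#' and standard deviation (used to justify log-scaling beta power before the
#' mixed model). Thin wrapper around [nortest::lillie.test()].
#'
#' @param values numeric sample, n >= 5, non-constant
#' @return list with `statistic` and `p_value`
#' @export
lilliefors_test <- function(values) {
  if (length(values) < 5) stop("need at least 5 observations")
  if (stats::sd(values) == 0) stop("constant input")
  lt <- nortest::lillie.test(values)
  list(statistic = unname(lt$statistic), p_value = lt$p.value)
}
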
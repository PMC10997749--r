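# Internal helpers shared across modules.

#' Derive a child seed from a master seed and a component key
#'
#' All randomness in the package flows from one integer master seed; each
#' signal component (background, peaks, ECG, ...) draws from its own stream
#' whose seed is a deterministic function of the master seed and a string key.
#' Keeps results below 2^31 so they are valid R integer seeds.
#'
#' @param seed master integer seed
#' @param key character stream label
#' @return an integer seed
#' @keywords internal
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  # multiplicative congruential mix, modulus 2^31 - 1 (prime)
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% m + 1)
  x <- (x * 48271) %% m
  x <- (x + h * 69621) %% m
  as.integer((x * 16807) %% m)
}

# Evaluate expr with a locally seeded RNG, restoring global state afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Colored Gaussian noise of length n with amplitude shape `amp` given on the
# one-sided rfft frequency grid (length floor(n/2)+1), unit variance before
# `scale`. Shape is applied in the frequency domain to white noise.
shaped_noise <- function(n, amp, scale = 1, mult = NULL) {
  if (scale == 0 || all(amp == 0)) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  a2 <- onesided_to_twosided(amp, n)
  # normalise so the *unmultiplied* shape gives unit variance, then scale;
  # `mult` (e.g. condition band factors) changes realised variance as intended
  nrm <- sqrt(mean(a2^2))
  g <- a2 / nrm
  if (!is.null(mult)) g <- g * onesided_to_twosided(mult, n)
  Re(stats::fft(W * g, inverse = TRUE)) / n * scale
}

# Mirror a one-sided (rfft, length floor(n/2)+1) magnitude vector to the full
# two-sided fft grid of length n.
onesided_to_twosided <- function(amp, n) {
  c(amp, rev(amp[2:(n - floor(n / 2))]))
}

# One-sided rfft frequency grid for n samples at `rate` Hz.
rfft_freqs <- function(n, rate) {
  seq(0, floor(n / 2)) * rate / n
}

# Forward-backward IIR filtering with odd-reflection end padding, so that
# edge transients decay inside the discarded pad rather than in the data.
filtfilt_pad <- function(flt, x, pad) {
  n <- length(x)
  pad <- min(n - 1, round(pad))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filtfilt(flt, xp)
  y[(pad + 1):(pad + n)]
}

# Zero-phase low-pass via a Blackman-windowed sinc FIR applied in the
# frequency domain (symmetric kernel => purely real transfer function).
# Reflection-padded; O(n log n) regardless of kernel length.
fft_fir_lowpass <- function(x, rate, cutoff, taps = 1025) {
  n <- length(x)
  if (taps %% 2 == 0) taps <- taps + 1
  half <- (taps - 1) / 2
  k <- (-half):half
  h <- 2 * cutoff / rate * sinc_fn(2 * cutoff / rate * k)
  w <- 0.42 + 0.5 * cos(pi * k / half) + 0.08 * cos(2 * pi * k / half)
  h <- h * w
  h <- h / sum(h)
  pad <- min(n - 1, half)
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  n2 <- stats::nextn(length(xp) + taps, c(2, 3, 5))
  xp <- c(xp, numeric(n2 - length(xp)))
  hf <- numeric(n2)
  hf[1:(half + 1)] <- h[(half + 1):taps]
  hf[(n2 - half + 1):n2] <- h[1:half]
  y <- Re(stats::fft(stats::fft(xp) * Re(stats::fft(hf)), inverse = TRUE)) / n2
  y[(pad + 1):(pad + n)]
}

sinc_fn <- function(u) ifelse(u == 0, 1, sin(pi * u) / (pi * u))

# Merge a list of [lo, hi] intervals (matrix n x 2) into disjoint union.
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(matrix(numeric(0), ncol = 2))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      k <- nrow(out)
      if (iv[i, 1] <= out[k, 2]) {
        out[k, 2] <- max(out[k, 2], iv[i, 2])
      } else {
        out <- rbind(out, iv[i, , drop = FALSE])
      }
    }
  }
  unname(out)
}

# Is time point t inside any row of interval matrix iv?
in_intervals <- function(t, iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(rep(FALSE, length(t)))
  res <- rep(FALSE, length(t))
  for (i in seq_len(nrow(iv))) {
    res <- res | (t >= iv[i, 1] & t <= iv[i, 2])
  }
  res
}
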
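#' @useDynLib eegpli, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Analytic signal via the frequency-domain Hilbert construction
#'
#' Returns the complex analytic signal \eqn{x + i H\{x\}} of a real vector:
#' the FFT is taken, negative-frequency coefficients are zeroed, positive
#' frequencies doubled (DC and Nyquist untouched), and the inverse transform
#' returned.  Instantaneous phase is `Arg()`, instantaneous amplitude
#' (envelope) is `Mod()` of the result.
#'
#' @param x numeric vector (one channel, one window).
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  if (!is.numeric(x) || anyNA(x)) stop("x must be a finite numeric vector")
  n <- length(x)
  if (n < 2L) stop("analytic signal needs at least 2 samples")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# analytic signal per row of a channels x samples matrix
analytic_matrix <- function(m) {
  t(apply(m, 1L, analytic_signal))
}

# Run code with a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# 1/f-shaped ("pink") Gaussian noise: white noise spectrally weighted by
# 1/sqrt(f), DC removed, rescaled to unit standard deviation.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(1, seq_len(n - 1L))            # avoid the DC singularity
  f <- pmin(f, n - f + 1L)              # fold to two-sided frequency index
  X <- X / sqrt(f)
  X[1L] <- 0
  x <- Re(stats::fft(X, inverse = TRUE) / n)
  x / stats::sd(x)
}

# Zero-phase 4th-order Butterworth band-pass applied to a vector.
narrowband_noise <- function(n, fs, lo, hi) {
  bp <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bp, stats::rnorm(n))
  x / stats::sd(x)
}

# Band power of one window: one-sided periodogram integrated over [lo, hi] Hz.
# Parseval: summing all bins recovers mean(x^2).
window_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  p2 <- Mod(X)^2 / n^2                  # two-sided
  nhalf <- floor(n / 2)
  freq <- (0:nhalf) * fs / n
  p1 <- p2[1:(nhalf + 1L)]
  if (n %% 2L == 0L) p1[2:nhalf] <- 2 * p1[2:nhalf]
  else if (nhalf >= 1L) p1[2:(nhalf + 1L)] <- 2 * p1[2:(nhalf + 1L)]
  sum(p1[freq >= lo & freq <= hi])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
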
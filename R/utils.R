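#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so library code never perturbs user-level randomness.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-item seed from a master seed
#'
#' Splitmix-style integer mixing kept below 2^31 so any single item of a
#' seeded collection (a recording in a dataset, a repeat in an experiment)
#' is reproducible in isolation.
#' @noRd
derive_seed <- function(master, i) {
  m <- as.double(master) %% 2147483647
  ((m * 48271 + as.double(i) * 16807 + 12345) %% 2147483647) + 1
}

next_pow2 <- function(n) {
  2^ceiling(log2(max(1, n)))
}

#' Analytic signal via the frequency-domain Hilbert transform
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Homomorphic amplitude envelope
#'
#' exp(lowpass(log(|analytic signal|))): the classic smooth envelope used to
#' localize heart sounds. `lp_hz` is the envelope bandwidth.
#' @noRd
homomorphic_envelope <- function(x, fs, lp_hz = 8) {
  amp <- abs(analytic_signal(x))
  amp[amp < 1e-12] <- 1e-12
  lp <- signal::butter(1, lp_hz / (fs / 2), type = "low")
  exp(signal::filtfilt(lp, log(amp)))
}

## Moment-based shape statistics in the fixed conventions used by the
## feature set: Fisher g1 skewness, non-excess kurtosis (Gaussian -> 3).
skewness_g1 <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

kurtosis_m4 <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  mean((x - m)^4) / m2^2
}

## mean/sd pair over a vector that may contain NA markers; sd needs >= 2
## non-missing values, mean >= 1.
mean_sd_pair <- function(x) {
  x <- x[is.finite(x)]
  c(
    if (length(x) >= 1) mean(x) else NA_real_,
    if (length(x) >= 2) stats::sd(x) else NA_real_
  )
}
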
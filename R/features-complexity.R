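## Cyclostationarity, higher-order statistics, and entropy features.

#' Degree-of-cyclostationarity and peak-sharpness from a CFSD estimate
#'
#' Given a cycle-frequency spectral density gamma on the alpha grid
#' (excluding alpha = 0), computes the normalized peak density
#' d(eta) = gamma(eta) / integral(gamma, 0..beta) with the rectangle rule,
#' where eta is the location of the largest peak inside `hr_band`, and
#' peak_sharpness = max(gamma) / median(gamma). A constant density gives
#' peak_sharpness = 1.
#' @noRd
cfsd_metrics <- function(gamma, alpha, beta = 10, hr_band = c(0.5, 2.5)) {
  keep <- alpha > 0 & alpha <= beta
  g <- gamma[keep]
  a <- alpha[keep]
  if (!length(g) || all(g == 0)) {
    return(list(d_eta = NA_real_, sharpness = NA_real_))
  }
  d_alpha <- a[2] - a[1]
  integral <- sum(g) * d_alpha
  in_band <- a >= hr_band[1] & a <= hr_band[2]
  eta_idx <- if (any(in_band)) which(in_band)[which.max(g[in_band])] else which.max(g)
  list(
    d_eta = g[eta_idx] / integral,
    sharpness = max(g) / stats::median(g)
  )
}

#' Cyclostationarity features (4)
#'
#' The recording is split into non-overlapping subsequences (default 3 s).
#' For each, the cycle-frequency spectral density is estimated as the DFT
#' magnitude of the demeaned squared Hilbert envelope; the basic cycle
#' frequency is the largest peak in the physiological heart-rate band
#' 0.5-2.5 Hz. Features are the mean and SD over subsequences of the
#' normalized peak density (degree of cyclostationarity, large for strictly
#' periodic beating) and of the peak sharpness max/median. With fewer than
#' two subsequences the SDs are missing.
#'
#' @param recording A preprocessed [pcg_recording] of at least one
#'   subsequence length.
#' @param subsequence_s Subsequence length in seconds.
#' @param beta Maximum cycle frequency considered, Hz.
#' @param hr_band Search band for the basic cycle frequency, Hz.
#' @return Named numeric vector of length 4.
#' @export
cyclostationarity_features <- function(recording, subsequence_s = 3,
                                       beta = 10, hr_band = c(0.5, 2.5)) {
  nm <- c("m_cyclostationarity_1", "sd_cyclostationarity_1",
          "m_cyclostationarity_2", "sd_cyclostationarity_2")
  out <- stats::setNames(rep(NA_real_, 4), nm)
  fs <- recording$sampling_rate
  sub_len <- round(subsequence_s * fs)
  n_sub <- length(recording$samples) %/% sub_len
  if (n_sub < 1) {
    stop("recording shorter than one subsequence (", subsequence_s, " s)")
  }
  d_eta <- sharp <- rep(NA_real_, n_sub)
  for (k in seq_len(n_sub)) {
    seg <- recording$samples[((k - 1) * sub_len + 1):(k * sub_len)]
    env2 <- Mod(analytic_signal(seg))^2
    env2 <- env2 - mean(env2)
    gamma <- Mod(stats::fft(env2))
    alpha <- (seq_along(gamma) - 1) * fs / length(gamma)
    m <- cfsd_metrics(gamma, alpha, beta = beta, hr_band = hr_band)
    d_eta[k] <- m$d_eta
    sharp[k] <- m$sharpness
  }
  out[c(1, 2)] <- mean_sd_pair(d_eta)
  out[c(3, 4)] <- mean_sd_pair(sharp)
  out
}

#' Higher-order-statistics features (16)
#'
#' Per-cycle skewness (Fisher's g1) and kurtosis (non-excess, Gaussian -> 3)
#' of each state's samples, summarized as mean and SD over cycles; state
#' order S1, S2, systole, diastole. Zero-variance slices are excluded.
#'
#' @param cycles Output of [pcg_cycles()].
#' @return Named numeric vector of length 16.
#' @export
hos_features <- function(cycles) {
  states <- c(s1 = "S1", s2 = "S2", systole = "sys", diastole = "dia")
  nm <- as.vector(vapply(states, function(s) {
    c(sprintf("m_%s_skewness", s), sprintf("sd_%s_skewness", s),
      sprintf("m_%s_kurtosis", s), sprintf("sd_%s_kurtosis", s))
  }, character(4)))
  out <- stats::setNames(rep(NA_real_, 16), nm)
  if (!length(cycles)) return(out)
  for (k in seq_along(states)) {
    slot <- names(states)[k]
    sk <- vapply(cycles, function(cy) {
      x <- cy[[slot]]
      if (length(x) < 4) return(c(NA_real_, NA_real_))
      c(skewness_g1(x), kurtosis_m4(x))
    }, numeric(2))
    lbl <- states[[k]]
    out[sprintf("%s_%s_skewness", c("m", "sd"), lbl)] <- mean_sd_pair(sk[1, ])
    out[sprintf("%s_%s_kurtosis", c("m", "sd"), lbl)] <- mean_sd_pair(sk[2, ])
  }
  out
}

chebyshev_pairs <- function(emb) {
  ## pairwise Chebyshev distances between rows, as a vector (i < j)
  as.vector(stats::dist(emb, method = "maximum"))
}

embed_rows <- function(x, m) {
  n <- length(x) - m + 1
  out <- matrix(0, n, m)
  for (j in seq_len(m)) out[, j] <- x[j:(j + n - 1)]
  out
}

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A/B), where B counts template pairs within Chebyshev
#' tolerance `r` at length `m` and A the same pairs at length `m + 1`
#' (templates restricted to the first `N - m` positions, pairs i < j).
#' A constant sequence gives 0. When no pairs match at length `m` (B = 0),
#' or none remain at `m + 1`, the value is missing rather than infinite.
#'
#' @param x Numeric sequence, length > `m + 1`.
#' @param m Template length.
#' @param r Tolerance (absolute units).
#' @return SampEn value, or `NA`.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  if (n <= m + 1) stop("sequence too short for sample entropy")
  n_templates <- n - m
  d_m <- chebyshev_pairs(embed_rows(x, m)[seq_len(n_templates), , drop = FALSE])
  B <- sum(d_m <= r)
  if (B == 0) return(NA_real_)
  d_m1 <- chebyshev_pairs(embed_rows(x, m + 1))
  A <- sum(d_m1 <= r)
  if (A == 0) return(NA_real_)
  -log(A / B)
}

fuzzy_phi <- function(emb, r, n_fuzzy) {
  d <- chebyshev_pairs(emb)
  mean(exp(-(d^n_fuzzy) / r))
}

#' Fuzzy measure entropy
#'
#' Combines a local and a global fuzzy entropy. Local template vectors are
#' centered by their own segment mean, global vectors by the global series
#' mean; similarity between vectors is the fuzzy membership
#' exp(-d^n / r) of their Chebyshev distance d. The value is
#' ln(phiL_m / phiL_{m+1}) + ln(phiG_m / phiG_{m+1}).
#'
#' @param x Numeric sequence, length > `m + 1`.
#' @param m Template length.
#' @param r_local,r_global Local and global tolerance parameters.
#' @param n_fuzzy Fuzzy membership power.
#' @return FuzzyMEn value, or `NA` when a similarity average degenerates
#'   to zero.
#' @export
fuzzy_measure_entropy <- function(x, m = 2, r_local = 0.2 * stats::sd(x),
                                  r_global = 0.2 * stats::sd(x),
                                  n_fuzzy = 2) {
  n <- length(x)
  if (n <= m + 1) stop("sequence too short for fuzzy measure entropy")
  center_local <- function(emb) emb - rowMeans(emb)
  center_global <- function(emb) emb - mean(x)
  phi <- function(mm, center, r) {
    emb <- embed_rows(x, mm)[seq_len(n - m), , drop = FALSE]
    fuzzy_phi(center(emb), r, n_fuzzy)
  }
  pl_m <- phi(m, center_local, r_local)
  pl_m1 <- phi(m + 1, center_local, r_local)
  pg_m <- phi(m, center_global, r_global)
  pg_m1 <- phi(m + 1, center_global, r_global)
  if (min(pl_m, pl_m1, pg_m, pg_m1) <= 0) return(NA_real_)
  log(pl_m / pl_m1) + log(pg_m / pg_m1)
}

#' Entropy features (16)
#'
#' Sample entropy and fuzzy measure entropy of every state slice (slices
#' are subsampled to at most 1000 Hz to bound the quadratic cost), with
#' tolerance r = 0.2 x slice SD, summarized as mean and SD over cycles.
#' State order: S1, S2, systole, diastole for SampEn, then the same for
#' FuzzyMEn.
#'
#' @param cycles Output of [pcg_cycles()].
#' @param sampling_rate Sampling rate in Hz.
#' @param m Template length.
#' @return Named numeric vector of length 16.
#' @export
entropy_features <- function(cycles, sampling_rate, m = 2) {
  states <- c(s1 = "S1", s2 = "S2", systole = "sys", diastole = "dia")
  nm <- c(
    as.vector(vapply(states, function(s) sprintf(c("m_SampEn_%s", "sd_SampEn_%s"), s),
                     character(2))),
    as.vector(vapply(states, function(s) sprintf(c("m_FuzzyMEn_%s", "sd_FuzzyMEn_%s"), s),
                     character(2)))
  )
  out <- stats::setNames(rep(NA_real_, 16), nm)
  if (!length(cycles)) return(out)
  stride <- max(1L, round(sampling_rate / 1000))

  for (k in seq_along(states)) {
    slot <- names(states)[k]
    vals <- vapply(cycles, function(cy) {
      x <- cy[[slot]][seq(1, length(cy[[slot]]), by = stride)]
      s <- stats::sd(x)
      if (length(x) <= m + 1 || !is.finite(s) || s == 0) {
        return(c(NA_real_, NA_real_))
      }
      c(sample_entropy(x, m, 0.2 * s),
        fuzzy_measure_entropy(x, m, 0.2 * s, 0.2 * s, 2))
    }, numeric(2))
    lbl <- states[[k]]
    out[sprintf(c("m_SampEn_%s", "sd_SampEn_%s"), lbl)] <- mean_sd_pair(vals[1, ])
    out[sprintf(c("m_FuzzyMEn_%s", "sd_FuzzyMEn_%s"), lbl)] <- mean_sd_pair(vals[2, ])
  }
  out
}
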
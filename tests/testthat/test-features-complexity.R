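# Brute-force oracles for the cepstrum, entropy, and moment features, plus
# the cyclostationarity metrics. Oracles are written as literal definitions
# (explicit DFT sums, exhaustive pairwise loops) independent of the package
# implementation.

naive_dft <- function(x, inverse = FALSE) {
  n <- length(x)
  sgn <- if (inverse) 1 else -1
  vapply(0:(n - 1), function(k) {
    sum(x * exp(sgn * 2i * pi * k * (0:(n - 1)) / n))
  }, complex(1))
}

test_that("real cepstrum equals the brute-force DFT->log->IDFT definition", {
  set.seed(11)
  x <- stats::rnorm(64)
  ours <- real_cepstrum(x)
  P <- Mod(naive_dft(x))
  oracle <- Re(naive_dft(log(P), inverse = TRUE)) / 64
  expect_equal(ours, oracle[1:13], tolerance = 1e-9)
  # coefficient 0 is the mean of the log-magnitude spectrum
  expect_equal(ours[1], mean(log(P)), tolerance = 1e-9)
})

test_that("cepstrum degenerate cases: impulse and zero floor", {
  imp <- c(1, numeric(63))            # |P(k)| = 1 for all k
  expect_equal(real_cepstrum(imp), numeric(13), tolerance = 1e-9)
  expect_error(real_cepstrum(numeric(10)), "too short")
  # exact zeros in the spectrum are floored, never -Inf
  x <- rep(c(1, -1), 32)              # spectrum concentrated at Nyquist
  expect_true(all(is.finite(real_cepstrum(x))))
})

test_that("cepstrum features join states consistently (65 values)", {
  r <- clean_fixture()
  fv <- cepstrum_features(r$prep, r$truth_segmentation)
  expect_length(fv, 65)
  # oracle by construction: explicit concatenation of S1 slices
  iv <- r$truth_segmentation$intervals
  s1_joined <- unlist(lapply(which(iv$state == "S1"), function(k) {
    r$prep$samples[(iv$start_sample[k] + 1):iv$end_sample[k]]
  }))
  expect_equal(as.numeric(fv[sprintf("Cep_S1_%d", 1:13)]),
               real_cepstrum(s1_joined), tolerance = 1e-12)
  expect_equal(as.numeric(fv[sprintf("Cep_record_%d", 1:13)]),
               real_cepstrum(r$prep$samples), tolerance = 1e-12)

  # single cycle: joined-S1 cepstrum equals that cycle's S1 cepstrum
  one <- pcg_segmentation(iv[1:4, ])
  fv1 <- cepstrum_features(r$prep, one)
  s1 <- r$prep$samples[(iv$start_sample[1] + 1):iv$end_sample[1]]
  expect_equal(as.numeric(fv1[sprintf("Cep_S1_%d", 1:13)]),
               real_cepstrum(s1), tolerance = 1e-12)
})

sampen_bruteforce <- function(x, m, r) {
  n <- length(x)
  count <- function(mm) {
    tot <- 0
    for (i in 1:(n - m - 1)) {
      for (j in (i + 1):(n - m)) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) tot <- tot + 1
      }
    }
    tot
  }
  B <- count(m)
  A <- count(m + 1)
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

test_that("sample entropy matches an exhaustive pairwise oracle", {
  set.seed(21)
  x <- stats::rnorm(50)
  r <- 0.2 * stats::sd(x)
  expect_equal(sample_entropy(x, 2, r), sampen_bruteforce(x, 2, r),
               tolerance = 1e-9)
  x2 <- sin(2 * pi * (1:50) / 10) + 0.1 * stats::rnorm(50)
  r2 <- 0.2 * stats::sd(x2)
  expect_equal(sample_entropy(x2, 2, r2), sampen_bruteforce(x2, 2, r2),
               tolerance = 1e-9)
})

test_that("sample entropy closed forms and ordering", {
  expect_identical(sample_entropy(rep(1, 30), 2, 0.1), 0)   # all match
  expect_error(sample_entropy(1:3, 2, 0.1), "too short")
  # i.i.d. noise is more irregular than a sinusoid at matched SD
  deltas <- vapply(1:10, function(s) {
    set.seed(s)
    noise <- stats::rnorm(300)
    tone <- sin(2 * pi * 5 * (1:300) / 300)
    tone <- tone / stats::sd(tone)
    sample_entropy(noise, 2, 0.2 * stats::sd(noise)) -
      sample_entropy(tone, 2, 0.2 * stats::sd(tone))
  }, numeric(1))
  expect_true(all(deltas > 0))
})

fuzzymen_bruteforce <- function(x, m, rl, rg, nf) {
  n <- length(x)
  nt <- n - m
  phi <- function(mm, local) {
    tot <- 0
    cnt <- 0
    for (i in 1:(nt - 1)) {
      for (j in (i + 1):nt) {
        xi <- x[i:(i + mm - 1)]
        xj <- x[j:(j + mm - 1)]
        if (local) {
          xi <- xi - mean(xi); xj <- xj - mean(xj)
          r <- rl
        } else {
          xi <- xi - mean(x); xj <- xj - mean(x)
          r <- rg
        }
        d <- max(abs(xi - xj))
        tot <- tot + exp(-(d^nf) / r)
        cnt <- cnt + 1
      }
    }
    tot / cnt
  }
  log(phi(m, TRUE) / phi(m + 1, TRUE)) + log(phi(m, FALSE) / phi(m + 1, FALSE))
}

test_that("fuzzy measure entropy matches an exhaustive oracle", {
  set.seed(31)
  x <- stats::rnorm(40)
  r <- 0.2 * stats::sd(x)
  expect_equal(fuzzy_measure_entropy(x, 2, r, r, 2),
               fuzzymen_bruteforce(x, 2, r, r, 2), tolerance = 1e-9)
})

test_that("entropy features: 16 values, zero SD for identical cycles", {
  r <- clean_fixture()
  fv <- entropy_features(r$cycles, 2000)
  expect_length(fv, 16)
  cy <- r$cycles[[1]]
  fv_same <- entropy_features(list(cy, cy, cy), 2000)
  expect_true(all(fv_same[grep("^sd_", names(fv_same))] == 0))
})

test_that("murmurs raise systolic sample entropy over seeded pairs", {
  deltas <- vapply(1:10, function(s) {
    n <- generate_recording(synth_config(seed = s, duration = 5))
    m <- generate_recording(synth_config(seed = s, duration = 5,
                                         murmur = "systolic",
                                         murmur_snr = 0))
    fn <- entropy_features(
      pcg_cycles(n$truth_segmentation, pcg_preprocess(n$recording)), 2000)
    fm <- entropy_features(
      pcg_cycles(m$truth_segmentation, pcg_preprocess(m$recording)), 2000)
    fm[["m_SampEn_sys"]] - fn[["m_SampEn_sys"]]
  }, numeric(1))
  expect_gt(mean(deltas > 0), 0.8)
})

test_that("skewness/kurtosis follow the stated conventions and moments", {
  # symmetric values -> zero skewness
  sym <- toy_amplitude_cycles(rbind(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  fv <- hos_features(sym)
  expect_length(fv, 16)
  expect_equal(fv[["m_S1_skewness"]], 0, tolerance = 1e-9)

  # moment oracle at n = 1e4: non-excess Gaussian kurtosis ~ 3
  set.seed(41)
  g <- stats::rnorm(1e4)
  cyc <- list(s1 = g, systole = g, s2 = g, diastole = g, cycle = rep(g, 4))
  fvg <- hos_features(list(cyc))
  expect_lt(abs(fvg[["m_S1_kurtosis"]] - 3), 0.2)
  # explicit moment-ratio oracle
  m2 <- mean((g - mean(g))^2); m3 <- mean((g - mean(g))^3)
  m4 <- mean((g - mean(g))^4)
  expect_equal(fvg[["m_S1_skewness"]], m3 / m2^1.5, tolerance = 1e-12)
  expect_equal(fvg[["m_S1_kurtosis"]], m4 / m2^2, tolerance = 1e-12)

  # zero-variance slices are excluded
  flat <- toy_amplitude_cycles(rbind(c(0, 1, 1, 1), c(0, 1, 1, 1)))
  flat <- lapply(flat, function(cy) { cy$s1 <- rep(2, 8); cy })
  expect_true(is.na(hos_features(flat)[["m_S1_skewness"]]))
})

test_that("cyclostationarity metrics behave per their closed forms", {
  # constant density (test seam): peak sharpness = max/median = 1
  m <- pcgclass:::cfsd_metrics(rep(2, 100), seq(0.1, 10, length.out = 100))
  expect_identical(m$sharpness, 1)

  r <- clean_fixture()
  fv <- cyclostationarity_features(r$prep)
  expect_length(fv, 4)
  expect_true(all(is.finite(fv)))

  # strictly periodic beating vs white noise: larger degree of
  # cyclostationarity, paired over 10 seeds
  deltas <- vapply(1:10, function(s) {
    p <- generate_recording(synth_config(seed = s))
    cp <- cyclostationarity_features(pcg_preprocess(p$recording))
    w <- with_seed_test(s, pcg_recording(stats::rnorm(20000), 2000))
    cw <- cyclostationarity_features(w)
    cp[["m_cyclostationarity_1"]] - cw[["m_cyclostationarity_1"]]
  }, numeric(1))
  expect_true(all(deltas > 0))

  # fewer than 2 subsequences: SDs missing, means defined
  short <- pcg_recording(r$prep$samples[1:7000], 2000)
  fs <- cyclostationarity_features(short)
  expect_true(is.na(fs[["sd_cyclostationarity_1"]]))
  expect_true(is.finite(fs[["m_cyclostationarity_1"]]))
})
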
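## Built-in four-state segmenter.
##
## A full logistic-regression HSMM is out of scope here; all downstream
## features depend only on the segmentation interface, so the segmenter is
## pluggable (pass external annotations wherever a segmentation is accepted)
## and the built-in decoder is deliberately simple:
##   1. homomorphic envelope, downsampled to a 50 Hz decision grid;
##   2. heart rate and systolic interval from the envelope autocorrelation;
##   3. duration-constrained Viterbi over the cyclic state order
##      S1 -> systole -> S2 -> diastole with Gaussian emissions on the
##      envelope and truncated-Gaussian duration priors.
## Ties are broken toward the earliest boundary by the fixed scan order.

#' Segment a PCG recording into the four heart-sound states
#'
#' @param recording A preprocessed [pcg_recording] of at least 2 s.
#' @param annotations Optional [pcg_segmentation] (e.g. from
#'   [read_annotations()]); when supplied it is range-checked against the
#'   recording and returned as-is, bypassing the built-in segmenter.
#' @param envelope_fs Decision-grid rate of the envelope, Hz.
#' @param s1_prior,s2_prior Mean and SD (seconds) of the S1/S2 duration
#'   priors. Defaults follow the large-scale duration statistics commonly
#'   used for heart-sound HSMMs (S1 122+/-49 ms, S2 92+/-35 ms).
#' @return A [pcg_segmentation].
#' @export
segment_pcg <- function(recording, annotations = NULL, envelope_fs = 50,
                        s1_prior = c(0.122, 0.049),
                        s2_prior = c(0.092, 0.035)) {
  fs <- recording$sampling_rate
  n <- length(recording$samples)
  if (!is.null(annotations)) {
    stopifnot(inherits(annotations, "pcg_segmentation"))
    if (max(annotations$intervals$end_sample) > n) {
      stop("annotations extend past the end of the recording")
    }
    return(annotations)
  }
  if (n / fs < 2) stop("recording too short to segment (< 2 s)")

  ## 1. envelope on the decision grid
  env_full <- homomorphic_envelope(recording$samples, fs)
  stride <- max(1L, round(fs / envelope_fs))
  env <- env_full[seq(1, n, by = stride)]
  efs <- fs / stride
  env <- (env - mean(env)) / max(stats::sd(env), 1e-12)
  T_ <- length(env)

  ## 2. heart rate from the envelope autocorrelation (30-200 bpm band)
  ac <- stats::acf(env, lag.max = min(T_ - 1, round(2.2 * efs)),
                   plot = FALSE)$acf[, 1, 1]
  lag_lo <- round(60 / 200 * efs)
  lag_hi <- min(length(ac) - 1, round(60 / 30 * efs))
  if (lag_hi <= lag_lo) stop("no plausible heart rate found (recording too short)")
  band <- ac[(lag_lo + 1):(lag_hi + 1)]
  is_peak <- c(FALSE, diff(sign(diff(band))) < 0, FALSE)
  cand <- which(is_peak & band > 0)
  if (!length(cand)) cand <- which.max(band)
  period_lag <- lag_lo + cand[which.max(band[cand])] - 1
  period_s <- period_lag / efs
  if (period_s < 60 / 200 || period_s > 60 / 30) {
    stop("no plausible heart rate found (autocorrelation peak outside 30-200 bpm)")
  }

  ## systolic interval (S1 onset -> S2 onset) from the early acf peak
  sys_lo <- round(0.15 * efs)
  sys_hi <- max(sys_lo + 1, round(period_lag / 2))
  sys_band <- ac[(sys_lo + 1):(sys_hi + 1)]
  sys_lag <- sys_lo + which.max(sys_band) - 1
  sys_interval_s <- max(sys_lag / efs, s1_prior[1] + 0.05)

  ## 3. duration priors on the envelope grid
  dur_mean_s <- c(
    S1 = s1_prior[1],
    systole = sys_interval_s - s1_prior[1],
    S2 = s2_prior[1],
    diastole = period_s - sys_interval_s - s2_prior[1]
  )
  dur_mean_s["diastole"] <- max(dur_mean_s["diastole"], 0.1)
  dur_mean_s["systole"] <- max(dur_mean_s["systole"], 0.05)
  dur_sd_s <- c(S1 = s1_prior[2], systole = 0.25 * dur_mean_s[["systole"]],
                S2 = s2_prior[2], diastole = 0.25 * dur_mean_s[["diastole"]])

  sound_state <- c(TRUE, FALSE, TRUE, FALSE) # S1, systole, S2, diastole
  hi <- env[env > stats::quantile(env, 0.7)]
  lo <- env[env <= stats::quantile(env, 0.7)]
  mu <- ifelse(sound_state, mean(hi), mean(lo))
  sd_e <- pmax(c(stats::sd(hi), stats::sd(lo))[2 - sound_state], 0.3)

  emis <- vapply(1:4, function(s) {
    stats::dnorm(env, mu[s], sd_e[s], log = TRUE)
  }, numeric(T_))
  cum_emis <- rbind(0, apply(emis, 2, cumsum))

  d_min <- pmax(2L, round((dur_mean_s - 2.5 * dur_sd_s) * efs))
  d_max <- pmax(d_min + 1L, round((dur_mean_s + 2.5 * dur_sd_s) * efs))
  dur_logp <- lapply(1:4, function(s) {
    d <- d_min[s]:d_max[s]
    lp <- stats::dnorm(d / efs, dur_mean_s[s], dur_sd_s[s], log = TRUE)
    lp - log(sum(exp(lp - max(lp))) ) - max(lp) # normalized over the support
  })

  prev_state <- c(4L, 1L, 2L, 3L)

  ## 4. Viterbi over segment ends
  NEG <- -1e18
  delta <- matrix(NEG, T_, 4)
  back_t <- matrix(0L, T_, 4)
  for (t in seq_len(T_)) {
    for (s in 1:4) {
      durs <- d_min[s]:d_max[s]
      durs <- durs[durs <= t]
      if (!length(durs)) next
      starts <- t - durs + 1L
      seg_ll <- cum_emis[t + 1, s] - cum_emis[starts, s]
      prior <- dur_logp[[s]][durs - d_min[s] + 1]
      prev_score <- numeric(length(starts))
      for (k in seq_along(starts)) {
        prev_score[k] <- if (starts[k] == 1L) 0 else delta[starts[k] - 1L, prev_state[s]]
      }
      tot <- prev_score + seg_ll + prior
      k_best <- which.max(tot)
      if (tot[k_best] > delta[t, s]) {
        delta[t, s] <- tot[k_best]
        back_t[t, s] <- starts[k_best]
      }
    }
  }

  s <- which.max(delta[T_, ])
  if (delta[T_, s] <= NEG) stop("segmentation failed (no admissible state path)")
  t <- T_
  segs <- list()
  while (t >= 1 && back_t[t, s] > 0) {
    st <- back_t[t, s]
    segs[[length(segs) + 1]] <- data.frame(
      state = PCG_STATES[s],
      start_sample = (st - 1) * stride,
      end_sample = min(t * stride, n)
    )
    s_next <- prev_state[s]
    t <- st - 1L
    s <- s_next
    if (t < 1) break
  }
  iv <- do.call(rbind, rev(segs))
  pcg_segmentation(iv)
}

#' Decompose a segmented recording into cardiac cycles
#'
#' Returns one element per complete S1 -> systole -> S2 -> diastole run;
#' trailing incomplete cycles are dropped. Each element holds the four state
#' slices and `cycle`, which is exactly their concatenation.
#'
#' @param segmentation A [pcg_segmentation].
#' @param recording The [pcg_recording] the segmentation refers to.
#' @return List of lists with elements `s1`, `systole`, `s2`, `diastole`,
#'   `cycle`, and `start_sample`.
#' @export
pcg_cycles <- function(segmentation, recording) {
  iv <- segmentation$intervals
  n <- length(recording$samples)
  if (max(iv$end_sample) > n) {
    stop("segmentation extends past the end of the recording")
  }
  s1_rows <- which(iv$state == "S1")
  out <- list()
  for (r in s1_rows) {
    if (r + 3 > nrow(iv)) next
    slice <- function(k) {
      recording$samples[(iv$start_sample[k] + 1):iv$end_sample[k]]
    }
    cyc <- list(
      s1 = slice(r), systole = slice(r + 1),
      s2 = slice(r + 2), diastole = slice(r + 3),
      start_sample = iv$start_sample[r]
    )
    cyc$cycle <- c(cyc$s1, cyc$systole, cyc$s2, cyc$diastole)
    out[[length(out) + 1]] <- cyc
  }
  out
}

#' Sample-wise agreement between two segmentations
#'
#' Fraction of samples covered by `truth` whose state label matches the
#' label assigned by `estimate` (samples the estimate leaves unlabeled count
#' as errors).
#'
#' @param estimate,truth [pcg_segmentation] objects over the same recording.
#' @param n_samples Length of the recording in samples.
#' @return Accuracy in \[0, 1\].
#' @export
segmentation_accuracy <- function(estimate, truth, n_samples) {
  label_vec <- function(seg) {
    v <- rep(NA_character_, n_samples)
    iv <- seg$intervals
    for (k in seq_len(nrow(iv))) {
      v[(iv$start_sample[k] + 1):min(iv$end_sample[k], n_samples)] <- iv$state[k]
    }
    v
  }
  lt <- label_vec(truth)
  le <- label_vec(estimate)
  keep <- !is.na(lt)
  mean(!is.na(le[keep]) & le[keep] == lt[keep])
}
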
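## Synthetic phonocardiogram generator.
##
## Emulates what the feature set exploits in real heart sounds: quasi-periodic
## cycles of four ordered states (S1, systole, S2, diastole), S1/S2 rendered
## as Hanning-windowed low-frequency two-tone bursts, optional broadband
## murmurs confined to the systolic and/or diastolic state, a stationary
## background noise floor, and optional heavy noise plus friction-like spikes
## for the poor-signal-quality class. Every draw is controlled by a single
## seed so ground truth is exact and reproducible.

#' Configuration for the synthetic PCG generator
#'
#' @param sampling_rate Sampling rate in Hz. The default 2000 Hz keeps the
#'   Nyquist frequency above the 820 Hz upper edge of the feature bands.
#' @param duration Recording length in seconds.
#' @param heart_rate_mean Mean heart rate in beats per minute.
#' @param heart_rate_jitter Fractional SD of the multiplicative Gaussian
#'   jitter on the cycle period (truncated at 3 SD so state durations stay
#'   feasible).
#' @param s1_duration,s2_duration S1 and S2 burst durations in seconds.
#' @param systole_fraction Duration of the systolic state as a fraction of
#'   the cycle period.
#' @param murmur `"none"`, `"systolic"`, `"diastolic"` or `"both"`.
#' @param murmur_band Murmur pass band in Hz (band-limited white noise).
#' @param murmur_snr Murmur level in dB relative to the RMS of the S1 burst;
#'   0 dB means murmur RMS equals S1 RMS.
#' @param noise_snr Signal-to-background-noise ratio in dB. `Inf` disables
#'   the noise floor entirely; values below 15 dB mark the recording as poor
#'   quality.
#' @param spike_rate Expected frequency of friction-spike artifacts in
#'   events per second; any positive rate marks the recording poor quality.
#' @param seed Integer seed that fully determines the output.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(sampling_rate = 2000, duration = 10,
                         heart_rate_mean = 72, heart_rate_jitter = 0.03,
                         s1_duration = 0.122, s2_duration = 0.092,
                         systole_fraction = 0.2,
                         murmur = c("none", "systolic", "diastolic", "both"),
                         murmur_band = c(150, 600), murmur_snr = -6,
                         noise_snr = 30, spike_rate = 0, seed = 1) {
  murmur <- match.arg(murmur)
  cfg <- list(
    sampling_rate = sampling_rate, duration = duration,
    heart_rate_mean = heart_rate_mean, heart_rate_jitter = heart_rate_jitter,
    s1_duration = s1_duration, s2_duration = s2_duration,
    systole_fraction = systole_fraction, murmur = murmur,
    murmur_band = murmur_band, murmur_snr = murmur_snr,
    noise_snr = noise_snr, spike_rate = spike_rate, seed = seed
  )
  for (f in c("duration", "heart_rate_mean", "s1_duration", "s2_duration",
              "systole_fraction")) {
    if (cfg[[f]] <= 0) stop("synth_config: ", f, " must be positive")
  }
  period <- 60 / heart_rate_mean
  shortest <- period * (1 - 3 * heart_rate_jitter)
  if (s1_duration + s2_duration + systole_fraction * shortest +
      0.05 >= shortest) {
    stop("synth_config: cycle cannot contain states (S1 + systole + S2 ",
         "leave no room for diastole at the configured heart rate)")
  }
  class(cfg) <- "synth_config"
  cfg
}

## Hanning-windowed two-tone burst, the transient model for S1/S2.
tone_burst <- function(len, fs, f1, f2, amp, phase1, phase2) {
  t <- (seq_len(len) - 1) / fs
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = len))
  amp * w * (sin(2 * pi * f1 * t + phase1) + 0.6 * sin(2 * pi * f2 * t + phase2))
}

rms <- function(x) sqrt(mean(x^2))

#' Generate one synthetic PCG recording with ground truth
#'
#' @param config A [synth_config].
#' @param record_id Identifier for the generated recording.
#' @return A list of class `synth_recording` with elements `recording`
#'   (a [pcg_recording] carrying the labels), `truth_segmentation`
#'   (a [pcg_segmentation]), `diagnosis_label` (+1 iff a murmur was
#'   injected), and `quality_label` (0 iff heavy noise or spikes were
#'   configured).
#' @export
generate_recording <- function(config = synth_config(), record_id = "rec") {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  diagnosis <- if (config$murmur == "none") -1L else 1L
  quality <- if (config$noise_snr < 15 || config$spike_rate > 0) 0L else 1L

  out <- with_seed(config$seed, {
    x <- numeric(n)
    base_period <- 60 / config$heart_rate_mean
    jit <- config$heart_rate_jitter
    intervals <- list()
    s1_rms_all <- numeric(0)
    t0 <- 0
    repeat {
      z <- max(-3, min(3, stats::rnorm(1)))
      period <- base_period * (1 + jit * z)
      min_period <- config$s1_duration + config$s2_duration +
        config$systole_fraction * period + 0.05
      if (period < min_period) period <- min_period
      if (t0 + period > config$duration + 1e-9) break

      d_s1 <- config$s1_duration
      d_sys <- config$systole_fraction * period
      d_s2 <- config$s2_duration
      b <- round(fs * cumsum(c(t0, d_s1, d_sys, d_s2)))
      b <- c(b, round(fs * (t0 + period)))
      if (any(diff(b) < 1)) break

      amp1 <- stats::runif(1, 0.9, 1.1)
      amp2 <- 0.7 * stats::runif(1, 0.9, 1.1)
      ph <- stats::runif(4, 0, 2 * pi)
      s1_seg <- tone_burst(b[2] - b[1], fs, 60, 110, amp1, ph[1], ph[2])
      s2_seg <- tone_burst(b[4] - b[3], fs, 85, 140, amp2, ph[3], ph[4])
      x[(b[1] + 1):b[2]] <- s1_seg
      x[(b[3] + 1):b[4]] <- s2_seg
      s1_rms_all <- c(s1_rms_all, rms(s1_seg))

      intervals[[length(intervals) + 1]] <- data.frame(
        state = PCG_STATES,
        start_sample = b[1:4],
        end_sample = b[2:5]
      )
      t0 <- t0 + period
    }
    if (!length(intervals)) {
      stop("synth: recording shorter than one cardiac cycle")
    }
    iv <- do.call(rbind, intervals)

    ## murmurs: band-limited white noise confined to the configured state(s)
    if (config$murmur != "none") {
      bp <- signal::butter(4, config$murmur_band / (fs / 2), type = "pass")
      target_rms <- mean(s1_rms_all) * 10^(config$murmur_snr / 20)
      states <- switch(config$murmur,
                       systolic = "systole",
                       diastolic = "diastole",
                       both = c("systole", "diastole"))
      for (k in which(iv$state %in% states)) {
        lo <- iv$start_sample[k] + 1
        hi <- iv$end_sample[k]
        len <- hi - lo + 1
        m <- signal::filter(bp, stats::rnorm(len + 200))[-(1:200)]
        ramp <- pmin(1, (seq_len(len) - 1) / (0.01 * fs),
                     (len - seq_len(len)) / (0.01 * fs))
        m <- m * pmax(ramp, 0)
        if (rms(m) > 0) m <- m * target_rms / rms(m)
        x[lo:hi] <- x[lo:hi] + m
      }
    }

    ## stationary background noise floor: low-pass rumble (< 100 Hz), the
    ## dominant color of ambient and contact noise in auscultation
    if (is.finite(config$noise_snr)) {
      lp <- signal::butter(2, 100 / (fs / 2), type = "low")
      noise <- signal::filter(lp, stats::rnorm(n + 200))[-(1:200)]
      sig_rms <- rms(x)
      x <- x + noise * sig_rms * 10^(-config$noise_snr / 20) / rms(noise)
    }

    ## friction-like spikes
    if (config$spike_rate > 0) {
      n_spikes <- stats::rpois(1, config$spike_rate * config$duration)
      if (n_spikes > 0) {
        amp <- 6 * max(abs(x))
        pos <- sample.int(n - 2, n_spikes) + 1
        for (p in pos) {
          s <- sample(c(-1, 1), 1) * amp
          x[(p - 1):(p + 1)] <- x[(p - 1):(p + 1)] + s * c(0.4, 1, 0.4)
        }
      }
    }
    list(x = x, iv = iv)
  })

  structure(
    list(
      recording = pcg_recording(out$x, fs, record_id = record_id,
                                diagnosis = diagnosis, quality = quality),
      truth_segmentation = pcg_segmentation(out$iv),
      diagnosis_label = diagnosis,
      quality_label = quality
    ),
    class = "synth_recording"
  )
}

#' Generate a labeled synthetic PCG dataset
#'
#' Produces `n_normal` murmur-free and `n_abnormal` murmur recordings;
#' `round(noisy_fraction * total)` of them (chosen at random across both
#' classes) are degraded with heavy noise (5 dB SNR) and spikes and labeled
#' poor quality. Per-recording seeds are derived deterministically from
#' `seed`, and heart rate (uniform 60-100 bpm), murmur type, and murmur
#' level vary across recordings.
#'
#' @param n_normal,n_abnormal Class counts (>= 0).
#' @param noisy_fraction Fraction of recordings rendered with poor quality.
#' @param seed Master seed.
#' @param config Template [synth_config]; per-recording fields
#'   (`heart_rate_mean`, `murmur`, `murmur_snr`, `noise_snr`, `spike_rate`,
#'   `seed`) are overridden per draw.
#' @return List of `synth_recording` objects, ids `rec001`, `rec002`, ...
#' @export
generate_dataset <- function(n_normal, n_abnormal, noisy_fraction = 0,
                             seed = 1, config = synth_config()) {
  stopifnot(n_normal >= 0, n_abnormal >= 0,
            noisy_fraction >= 0, noisy_fraction <= 1)
  total <- n_normal + n_abnormal
  if (total == 0) return(list())

  plan <- with_seed(seed, {
    n_noisy <- round(noisy_fraction * total)
    noisy <- rep(FALSE, total)
    if (n_noisy > 0) noisy[sample.int(total, n_noisy)] <- TRUE
    data.frame(
      abnormal = rep(c(FALSE, TRUE), c(n_normal, n_abnormal)),
      noisy = noisy,
      hr = stats::runif(total, 60, 100),
      murmur_type = sample(c("systolic", "diastolic", "both"), total,
                           replace = TRUE, prob = c(0.5, 0.3, 0.2)),
      murmur_snr = config$murmur_snr + stats::runif(total, -3, 3)
    )
  })

  lapply(seq_len(total), function(i) {
    cfg <- config
    cfg$heart_rate_mean <- plan$hr[i]
    cfg$murmur <- if (plan$abnormal[i]) plan$murmur_type[i] else "none"
    cfg$murmur_snr <- plan$murmur_snr[i]
    if (plan$noisy[i]) {
      cfg$noise_snr <- 5
      cfg$spike_rate <- 0.5
    }
    cfg$seed <- derive_seed(seed, i)
    generate_recording(cfg, record_id = sprintf("rec%03d", i))
  })
}

#' Reference-label table of a synthetic dataset
#'
#' @param dataset List of `synth_recording` objects.
#' @return Data frame with columns `record_id`, `diagnosis`, `quality`.
#' @export
synth_labels <- function(dataset) {
  data.frame(
    record_id = vapply(dataset, function(r) r$recording$record_id, ""),
    diagnosis = vapply(dataset, function(r) r$diagnosis_label, integer(1)),
    quality = vapply(dataset, function(r) r$quality_label, integer(1))
  )
}

#' Write a synthetic dataset to a directory
#'
#' One WAV and one `<id>_states.csv` ground-truth annotation file per
#' recording, plus `labels.csv`.
#'
#' @param dataset List of `synth_recording` objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in dataset) {
    id <- r$recording$record_id
    write_wav(r$recording, file.path(dir, paste0(id, ".wav")))
    write_annotations(r$truth_segmentation,
                      file.path(dir, paste0(id, "_states.csv")))
  }
  write_labels(synth_labels(dataset), file.path(dir, "labels.csv"))
  invisible(dir)
}
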
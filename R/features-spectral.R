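## Per-state spectra, whole-record spectrum ratios, and cepstrum features.

#' Per-state frequency-spectrum features (308)
#'
#' For each state of each cycle the slice is multiplied by a Gaussian window
#' (SD = length/6), zero-padded to a power of two giving at most 10 Hz bin
#' spacing, and transformed by DFT. Magnitudes are normalized by the slice
#' length, averaged over cycles, and sampled at the nearest bin to each of
#' the 77 grid frequencies 30, 40, ..., 790 Hz; states are ordered S1,
#' systole, S2, diastole.
#'
#' @param cycles Output of [pcg_cycles()].
#' @param sampling_rate Sampling rate in Hz; `sampling_rate/2` must exceed
#'   790 Hz.
#' @return Named numeric vector of length 308.
#' @export
state_spectrum_features <- function(cycles, sampling_rate) {
  grid <- state_grid()
  nm <- as.vector(vapply(c("S1", "sys", "S2", "dia"),
                         function(s) sprintf("Spec_%s_%dHz", s, grid),
                         character(77)))
  out <- stats::setNames(rep(NA_real_, 308), nm)
  if (!length(cycles)) return(out)
  if (sampling_rate / 2 <= 790) {
    stop("sampling rate too low for the 790 Hz grid point")
  }

  slice_spectrum <- function(x) {
    L <- length(x)
    idx <- seq_len(L) - (L + 1) / 2
    w <- exp(-0.5 * (idx / (L / 6))^2)
    N <- next_pow2(max(L, ceiling(sampling_rate / 10)))
    mag <- Mod(stats::fft(c(x * w, numeric(N - L)))) / L
    bins <- pmin(N, round(grid * N / sampling_rate) + 1)
    mag[bins]
  }

  states <- c(s1 = "S1", systole = "sys", s2 = "S2", diastole = "dia")
  for (k in seq_along(states)) {
    slot <- names(states)[k]
    specs <- vapply(cycles, function(cy) slice_spectrum(cy[[slot]]),
                    numeric(77))
    out[sprintf("Spec_%s_%dHz", states[[k]], grid)] <- rowMeans(specs)
  }
  out
}

#' Whole-record spectrum-ratio features (27)
#'
#' DFT of the full recording; each feature is the sum of spectrum magnitudes
#' in one of the 27 bands divided by the magnitude sum over the whole
#' 10-820 Hz band. Bins are assigned to half-open bands \[a, b), so shared
#' edges are unambiguous, and the 27 ratios sum to one.
#'
#' @param recording A preprocessed [pcg_recording].
#' @return Named numeric vector of length 27.
#' @export
record_spectrum_features <- function(recording) {
  x <- recording$samples
  fs <- recording$sampling_rate
  if (all(x == 0)) stop("zero recording")
  mag <- Mod(stats::fft(x))
  freq <- (seq_along(x) - 1) * fs / length(x)
  e <- band_edges()
  in_whole <- freq >= 10 & freq < 820
  total <- sum(mag[in_whole])
  vals <- vapply(1:27, function(i) {
    sum(mag[freq >= e[i] & freq < e[i + 1]]) / total
  }, numeric(1))
  stats::setNames(vals, sprintf("Ratio_spec_mag_%s",
                                vapply(1:27, band_label, "")))
}

#' Real cepstrum: first 13 coefficients
#'
#' The real cepstrum is the inverse DFT of the natural log of the DFT
#' magnitude. Zero magnitudes are floored at `1e-12 * max |P(k)|` so the
#' log is always finite. Coefficients 0..12 are returned; coefficient 0
#' equals the mean of the log-magnitude spectrum.
#'
#' @param x Numeric sequence, length >= 26.
#' @return Numeric vector of length 13.
#' @export
real_cepstrum <- function(x) {
  n <- length(x)
  if (n < 26) stop("sequence too short for cepstrum (need >= 26 samples)")
  P <- Mod(stats::fft(x))
  floor_at <- 1e-12 * max(P)
  if (max(P) == 0) return(rep(NA_real_, 13))
  P[P < floor_at] <- floor_at
  ceps <- Re(stats::fft(log(P), inverse = TRUE)) / n
  ceps[1:13]
}

#' Cepstrum-domain features (65)
#'
#' First 13 cepstral coefficients of five sequences: the whole record, and
#' the concatenation of all S1, systole, S2, and diastole intervals (in
#' that order). Sequences shorter than 26 samples yield missing values.
#'
#' @param recording A preprocessed [pcg_recording].
#' @param segmentation A [pcg_segmentation].
#' @return Named numeric vector of length 65.
#' @export
cepstrum_features <- function(recording, segmentation) {
  nm <- as.vector(vapply(c("record", "S1", "sys", "S2", "dia"),
                         function(s) sprintf("Cep_%s_%d", s, 1:13),
                         character(13)))
  out <- stats::setNames(rep(NA_real_, 65), nm)
  iv <- segmentation$intervals

  joined <- function(state) {
    rows <- which(iv$state == state)
    if (!length(rows)) return(numeric(0))
    unlist(lapply(rows, function(k) {
      recording$samples[(iv$start_sample[k] + 1):iv$end_sample[k]]
    }))
  }
  seqs <- list(
    record = recording$samples,
    S1 = joined("S1"), sys = joined("systole"),
    S2 = joined("S2"), dia = joined("diastole")
  )
  for (s in names(seqs)) {
    if (length(seqs[[s]]) >= 26) {
      out[sprintf("Cep_%s_%d", s, 1:13)] <- real_cepstrum(seqs[[s]])
    }
  }
  out
}
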
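## Preprocessing chain applied to every recording before segmentation and
## feature extraction, in this fixed order:
##   1. 10 Hz high-pass (baseline-drift removal)
##   2. spike removal (Schmidt-style windowed median rule)
##   3. normalization to zero mean, unit standard deviation

#' High-pass filter a recording at 10 Hz
#'
#' Order-2 Butterworth applied forward-backward ([signal::filtfilt()]), so
#' the filter is zero-phase and state boundaries are not shifted.
#'
#' @param recording A [pcg_recording].
#' @param cutoff_hz Cut-off frequency in Hz.
#' @param order Butterworth order (applied twice by filtfilt).
#' @return The filtered recording.
#' @export
pcg_highpass <- function(recording, cutoff_hz = 10, order = 2) {
  fs <- recording$sampling_rate
  hp <- signal::butter(order, cutoff_hz / (fs / 2), type = "high")
  recording$samples <- signal::filtfilt(hp, recording$samples)
  recording
}

#' Remove isolated high-amplitude spikes
#'
#' Schmidt-style procedure: the signal is split into fixed-length windows and
#' the maximum absolute amplitude (MAA) of each window is computed. While any
#' window's MAA exceeds `factor` times the median MAA, the largest spike is
#' located and the signal is zeroed from the last zero-crossing before it to
#' the first zero-crossing after it. Non-spike regions are left untouched.
#'
#' @param recording A [pcg_recording].
#' @param window_s Window length in seconds.
#' @param factor MAA-to-median threshold.
#' @return The despiked recording.
#' @export
pcg_remove_spikes <- function(recording, window_s = 0.5, factor = 3) {
  x <- recording$samples
  fs <- recording$sampling_rate
  wlen <- max(2L, round(window_s * fs))
  n <- length(x)
  n_win <- n %/% wlen
  if (n_win < 1) return(recording)
  use <- n_win * wlen

  for (iter in seq_len(1000L)) {
    maa <- vapply(seq_len(n_win), function(w) {
      max(abs(x[((w - 1) * wlen + 1):(w * wlen)]))
    }, numeric(1))
    med <- stats::median(maa)
    if (med <= 0 || max(maa) <= factor * med) break
    w <- which.max(maa)
    lo <- (w - 1) * wlen + 1
    hi <- w * wlen
    pos <- lo - 1 + which.max(abs(x[lo:hi]))
    ## walk out to the surrounding zero crossings
    i0 <- pos
    while (i0 > 1 && sign(x[i0]) == sign(x[pos]) && x[i0] != 0) i0 <- i0 - 1
    i1 <- pos
    while (i1 < use && sign(x[i1]) == sign(x[pos]) && x[i1] != 0) i1 <- i1 + 1
    x[i0:i1] <- 0
  }
  recording$samples <- x
  recording
}

#' Normalize a recording to zero mean and unit standard deviation
#'
#' @param recording A [pcg_recording].
#' @return The normalized recording.
#' @export
pcg_normalize <- function(recording) {
  s <- stats::sd(recording$samples)
  if (!is.finite(s) || s == 0) {
    stop("recording '", recording$record_id,
         "': cannot normalize a constant signal (zero variance)")
  }
  recording$samples <- (recording$samples - mean(recording$samples)) / s
  recording
}

#' Apply the full preprocessing chain
#'
#' High-pass at 10 Hz, spike removal, then normalization, in that order.
#'
#' @param recording A [pcg_recording].
#' @inheritParams pcg_highpass
#' @inheritParams pcg_remove_spikes
#' @return The preprocessed recording.
#' @export
pcg_preprocess <- function(recording, cutoff_hz = 10, window_s = 0.5,
                           factor = 3) {
  recording <- pcg_highpass(recording, cutoff_hz = cutoff_hz)
  recording <- pcg_remove_spikes(recording, window_s = window_s,
                                 factor = factor)
  pcg_normalize(recording)
}
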
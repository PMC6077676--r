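## Time-interval, normalized-amplitude and energy-domain features.
## All are per-beat quantities summarized as mean and SD over cycles;
## quantities that cannot be computed are marked NA (missing), never zeroed.

#' Time-interval features (20)
#'
#' Means and SDs of the RR interval (time between consecutive S1 onsets),
#' the four state intervals, and the per-beat ratios systole/RR,
#' diastole/RR, systole/diastole, S1/RR and S2/RR. Intervals are in
#' seconds; ratios are dimensionless. Per-beat ratios involving RR use
#' beats 1..(N-1), the beats for which an RR interval exists.
#'
#' @param segmentation A [pcg_segmentation].
#' @param sampling_rate Sampling rate in Hz of the segmented recording.
#' @return Named numeric vector of length 20; all `NA` when fewer than two
#'   complete cycles are available.
#' @export
time_interval_features <- function(segmentation, sampling_rate) {
  out <- stats::setNames(rep(NA_real_, 20), time_interval_names)
  iv <- segmentation$intervals
  s1_rows <- which(iv$state == "S1")
  s1_rows <- s1_rows[s1_rows + 3 <= nrow(iv)]
  N <- length(s1_rows)
  if (N < 2) return(out)

  len_s <- function(rows) (iv$end_sample[rows] - iv$start_sample[rows]) / sampling_rate
  int_s1 <- len_s(s1_rows)
  int_sys <- len_s(s1_rows + 1)
  int_s2 <- len_s(s1_rows + 2)
  int_dia <- len_s(s1_rows + 3)
  rr <- diff(iv$start_sample[s1_rows]) / sampling_rate # N-1 values

  b <- seq_len(N - 1) # beats with an RR interval
  vals <- c(
    mean_sd_pair(rr),
    mean_sd_pair(int_s1), mean_sd_pair(int_s2),
    mean_sd_pair(int_sys), mean_sd_pair(int_dia),
    mean_sd_pair(int_sys[b] / rr), mean_sd_pair(int_dia[b] / rr),
    mean_sd_pair(int_sys / int_dia),
    mean_sd_pair(int_s1[b] / rr), mean_sd_pair(int_s2[b] / rr)
  )
  stats::setNames(vals, time_interval_names)
}

#' Normalized amplitude features (12)
#'
#' Mean and SD over heart beats of the ratio of mean absolute amplitudes
#' between states: systole/S1, diastole/S2, S1/S2, S1/diastole,
#' systole/diastole, S2/systole. Beats whose denominator state has zero
#' mean absolute amplitude are excluded from that ratio's statistics.
#'
#' @param cycles Output of [pcg_cycles()].
#' @return Named numeric vector of length 12.
#' @export
amplitude_features <- function(cycles) {
  out <- stats::setNames(rep(NA_real_, 12), amplitude_names)
  if (!length(cycles)) return(out)
  maa <- vapply(cycles, function(cy) {
    c(s1 = mean(abs(cy$s1)), sys = mean(abs(cy$systole)),
      s2 = mean(abs(cy$s2)), dia = mean(abs(cy$diastole)))
  }, numeric(4))
  ratio <- function(num, den) {
    v <- maa[num, ] / maa[den, ]
    v[maa[den, ] == 0] <- NA_real_
    v
  }
  pairs <- list(c("sys", "s1"), c("dia", "s2"), c("s1", "s2"),
                c("s1", "dia"), c("sys", "dia"), c("s2", "sys"))
  vals <- unlist(lapply(pairs, function(p) mean_sd_pair(ratio(p[1], p[2]))))
  stats::setNames(vals, amplitude_names)
}

#' Band-energy ratio features (27)
#'
#' The recording is passed through 27 fifth-order Butterworth band-pass
#' filters on the contiguous 30 Hz bands \[10,40\], \[40,70\], ...,
#' \[790,820\] Hz; each feature is the filtered signal's energy divided by
#' the total energy of the unfiltered recording.
#'
#' @param recording A preprocessed [pcg_recording]; `sampling_rate/2` must
#'   exceed 820 Hz.
#' @return Named numeric vector of length 27.
#' @export
band_energy_features <- function(recording) {
  x <- recording$samples
  fs <- recording$sampling_rate
  if (fs / 2 <= 820) stop("sampling rate too low for the 820 Hz band edge")
  e_tot <- sum(x^2)
  if (e_tot == 0) stop("zero-energy recording")
  e <- band_edges()
  vals <- vapply(1:27, function(i) {
    bf <- signal::butter(5, c(e[i], e[i + 1]) / (fs / 2), type = "pass")
    y <- signal::filter(bf, x)
    sum(y^2) / e_tot
  }, numeric(1))
  stats::setNames(vals, sprintf("Ratio_band_energy_%s",
                                vapply(1:27, band_label, "")))
}

#' State-energy ratio features (20)
#'
#' Per cycle, the energy (sum of squares) of each state relative to the
#' whole cycle (4 ratios) and between state pairs S1/S2, S1/systole,
#' S1/diastole, S2/systole, S2/diastole, diastole/systole (6 ratios);
#' features are the mean and SD of each ratio over cycles. Cycles with a
#' zero-energy denominator are excluded from that ratio.
#'
#' @param cycles Output of [pcg_cycles()].
#' @return Named numeric vector of length 20.
#' @export
state_energy_features <- function(cycles) {
  nm <- as.vector(rbind(paste0("m_Ratio_state_energy_", energy_ratio_pairs),
                        paste0("sd_Ratio_state_energy_", energy_ratio_pairs)))
  out <- stats::setNames(rep(NA_real_, 20), nm)
  if (!length(cycles)) return(out)
  en <- vapply(cycles, function(cy) {
    c(s1 = sum(cy$s1^2), sys = sum(cy$systole^2),
      s2 = sum(cy$s2^2), dia = sum(cy$diastole^2),
      cycle = sum(cy$cycle^2))
  }, numeric(5))
  ratio <- function(num, den) {
    v <- en[num, ] / en[den, ]
    v[en[den, ] == 0] <- NA_real_
    v
  }
  pairs <- list(
    c("s1", "cycle"), c("s2", "cycle"), c("sys", "cycle"), c("dia", "cycle"),
    c("s1", "s2"), c("s1", "sys"), c("s1", "dia"),
    c("s2", "sys"), c("s2", "dia"), c("dia", "sys")
  )
  vals <- unlist(lapply(pairs, function(p) mean_sd_pair(ratio(p[1], p[2]))))
  stats::setNames(vals, nm)
}
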
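#' Construct a PCG recording object
#'
#' The basic container passed through the pipeline: a single-channel heart
#' sound signal with its sampling rate and optional reference labels.
#'
#' @param samples Numeric vector of signal samples (dimensionless after
#'   normalization).
#' @param sampling_rate Sampling rate in Hz. Full-band feature extraction
#'   (bands up to 820 Hz) requires `sampling_rate > 1640`.
#' @param record_id Character identifier.
#' @param diagnosis Optional reference diagnosis: `+1` abnormal, `-1` normal.
#' @param quality Optional reference signal quality: `1` clean, `0` noisy.
#' @return An object of class `pcg_recording`.
#' @export
pcg_recording <- function(samples, sampling_rate, record_id = "rec",
                          diagnosis = NA_integer_, quality = NA_integer_) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) {
    stop("recording '", record_id, "': samples must be finite")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a positive scalar")
  }
  if (!is.na(diagnosis) && !diagnosis %in% c(1L, -1L)) {
    stop("diagnosis must be +1 (abnormal), -1 (normal) or NA")
  }
  if (!is.na(quality) && !quality %in% c(1L, 0L)) {
    stop("quality must be 1 (clean), 0 (noisy) or NA")
  }
  structure(
    list(
      record_id = as.character(record_id),
      samples = samples,
      sampling_rate = as.numeric(sampling_rate),
      diagnosis = as.integer(diagnosis),
      quality = as.integer(quality)
    ),
    class = "pcg_recording"
  )
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf(
    "<pcg_recording> '%s': %d samples @ %g Hz (%.2f s)\n",
    x$record_id, length(x$samples), x$sampling_rate,
    length(x$samples) / x$sampling_rate
  ))
  if (!is.na(x$diagnosis)) {
    cat("  diagnosis:", if (x$diagnosis == 1) "abnormal (+1)" else "normal (-1)", "\n")
  }
  if (!is.na(x$quality)) {
    cat("  quality:  ", if (x$quality == 1) "clean (1)" else "noisy (0)", "\n")
  }
  invisible(x)
}

#' Plot a PCG recording with optional state overlay
#'
#' @param x A `pcg_recording`.
#' @param segmentation Optional `pcg_segmentation` whose intervals are shaded
#'   by state.
#' @param ... Passed to [graphics::plot()].
#' @method plot pcg_recording
#' @export
plot.pcg_recording <- function(x, segmentation = NULL, ...) {
  t <- seq_along(x$samples) / x$sampling_rate
  graphics::plot(t, x$samples, type = "l", xlab = "time [s]",
                 ylab = "amplitude", main = x$record_id, ...)
  if (!is.null(segmentation)) {
    cols <- c(S1 = "#d6604d55", systole = "#f4a58255",
              S2 = "#4393c355", diastole = "#92c5de55")
    iv <- segmentation$intervals
    for (k in seq_len(nrow(iv))) {
      graphics::rect(iv$start_sample[k] / x$sampling_rate, min(x$samples),
                     iv$end_sample[k] / x$sampling_rate, max(x$samples),
                     col = cols[[iv$state[k]]], border = NA)
    }
  }
  invisible(x)
}
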
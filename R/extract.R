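#' Extract the full 515-feature vector from a recording
#'
#' Runs the nine domain extractors and concatenates them in the canonical
#' order: time intervals (20), per-state spectra (308), normalized
#' amplitudes (12), energies (47), record spectrum (27), cepstrum (65),
#' cyclostationarity (4), higher-order statistics (16), entropy (16).
#' Features that cannot be computed on the given input are `NA` (imputed at
#' model-fitting time, never fabricated here).
#'
#' @param recording A preprocessed [pcg_recording].
#' @param segmentation A [pcg_segmentation] for the recording (ground-truth
#'   annotations or the output of [segment_pcg()]).
#' @return Named numeric vector of length 515 with attribute `domain`;
#'   class `pcg_features`.
#' @export
extract_features <- function(recording, segmentation) {
  if (!inherits(segmentation, "pcg_segmentation")) {
    stop("extract_features needs a valid segmentation")
  }
  fs <- recording$sampling_rate
  cycles <- pcg_cycles(segmentation, recording)
  v <- c(
    time_interval_features(segmentation, fs),
    state_spectrum_features(cycles, fs),
    amplitude_features(cycles),
    band_energy_features(recording),
    state_energy_features(cycles),
    record_spectrum_features(recording),
    cepstrum_features(recording, segmentation),
    cyclostationarity_features(recording),
    hos_features(cycles),
    entropy_features(cycles, fs)
  )
  schema <- pcg_feature_names()
  stopifnot(identical(names(v), schema$name))
  structure(v, domain = schema$domain, class = "pcg_features")
}

#' @export
print.pcg_features <- function(x, ...) {
  cat("<pcg_features> 515 features;", sum(!is.finite(unclass(x))),
      "missing\n")
  tab <- table(attr(x, "domain"))[unique(attr(x, "domain"))]
  cat(paste(sprintf("  %s: %d", names(tab), tab), collapse = "\n"), "\n")
  invisible(x)
}

#' Extract a feature table from a synthetic dataset
#'
#' Preprocesses every recording and extracts the 515 features, using either
#' the ground-truth annotations carried by the dataset or the built-in
#' segmenter.
#'
#' @param dataset List of `synth_recording` objects from
#'   [generate_dataset()], or a list of lists with elements `recording` and
#'   (for `segmenter = "truth"`) `truth_segmentation`.
#' @param segmenter `"truth"` or `"builtin"`.
#' @param preprocess Apply [pcg_preprocess()] first (recommended).
#' @return Data frame: `record_id` column plus the 515 canonical feature
#'   columns.
#' @export
extract_feature_table <- function(dataset, segmenter = c("truth", "builtin"),
                                  preprocess = TRUE) {
  segmenter <- match.arg(segmenter)
  rows <- lapply(dataset, function(r) {
    rec <- r$recording
    if (preprocess) rec <- pcg_preprocess(rec)
    seg <- if (segmenter == "truth") r$truth_segmentation else segment_pcg(rec)
    as.list(extract_features(rec, seg))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame, check.names = FALSE))
  cbind(
    data.frame(record_id = vapply(dataset, function(r) r$recording$record_id, "")),
    out
  )
}
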
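## State segmentation container and the CSV dialects used on disk.
## Coordinates are 0-based sample indices and intervals are half-open
## [start_sample, end_sample), in every file this package reads or writes.

PCG_STATES <- c("S1", "systole", "S2", "diastole")

state_successor <- c(S1 = "systole", systole = "S2", S2 = "diastole",
                     diastole = "S1")

#' Construct a four-state segmentation
#'
#' @param intervals Data frame with columns `state` (one of `"S1"`,
#'   `"systole"`, `"S2"`, `"diastole"`), `start_sample`, `end_sample`
#'   (0-based, half-open).
#' @return A `pcg_segmentation` with element `n_cycles`, the number of
#'   complete S1 -> systole -> S2 -> diastole runs.
#' @export
pcg_segmentation <- function(intervals) {
  intervals <- as.data.frame(intervals)
  needed <- c("state", "start_sample", "end_sample")
  if (!all(needed %in% names(intervals))) {
    stop("intervals must have columns: ", paste(needed, collapse = ", "))
  }
  intervals <- intervals[needed]
  intervals$state <- as.character(intervals$state)
  intervals$start_sample <- as.numeric(intervals$start_sample)
  intervals$end_sample <- as.numeric(intervals$end_sample)

  n <- nrow(intervals)
  if (n == 0) stop("segmentation has no intervals")
  bad_state <- which(!intervals$state %in% PCG_STATES)
  if (length(bad_state)) {
    stop("unknown state '", intervals$state[bad_state[1]], "' at interval ",
         bad_state[1])
  }
  if (any(intervals$end_sample <= intervals$start_sample)) {
    k <- which(intervals$end_sample <= intervals$start_sample)[1]
    stop("empty or inverted interval at row ", k)
  }
  if (n > 1) {
    gap <- intervals$start_sample[-1] - intervals$end_sample[-n]
    if (any(gap < 0)) {
      k <- which(gap < 0)[1]
      stop("overlapping or out-of-order intervals at rows ", k, "-", k + 1)
    }
    expected <- state_successor[intervals$state[-n]]
    if (any(expected != intervals$state[-1])) {
      k <- which(expected != intervals$state[-1])[1]
      stop("states out of cyclic order at rows ", k, "-", k + 1, ": ",
           intervals$state[k], " -> ", intervals$state[k + 1])
    }
  }

  s1_idx <- which(intervals$state == "S1")
  n_cycles <- sum(s1_idx + 3 <= n)
  structure(
    list(intervals = intervals, n_cycles = n_cycles),
    class = "pcg_segmentation"
  )
}

#' @export
print.pcg_segmentation <- function(x, ...) {
  cat(sprintf("<pcg_segmentation> %d intervals, %d complete cycles\n",
              nrow(x$intervals), x$n_cycles))
  invisible(x)
}

#' Read a state-annotation CSV
#'
#' Expects header `state,start_sample,end_sample`; 0-based half-open
#' intervals. Malformed or out-of-order rows raise an error naming the line.
#'
#' @param path CSV path.
#' @return A [pcg_segmentation].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("state", "start_sample", "end_sample"))) {
    stop(path, ": header must be 'state,start_sample,end_sample'")
  }
  for (col in c("start_sample", "end_sample")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) {
      stop(path, " line ", bad[1] + 1, ": non-numeric ", col)
    }
  }
  tryCatch(
    pcg_segmentation(df),
    error = function(e) stop(path, ": ", conditionMessage(e), call. = FALSE)
  )
}

#' Write a state-annotation CSV
#'
#' @param segmentation A [pcg_segmentation].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(segmentation, path) {
  utils::write.csv(segmentation$intervals, path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write reference-label tables
#'
#' CSV with header `record_id,diagnosis,quality`; diagnosis is +1 (abnormal)
#' or -1 (normal), quality 1 (clean) or 0 (noisy).
#'
#' @param path CSV path.
#' @return A data frame with one row per recording.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("record_id", "diagnosis", "quality"))) {
    stop(path, ": header must be 'record_id,diagnosis,quality'")
  }
  if (!all(df$diagnosis %in% c(1, -1))) stop(path, ": diagnosis must be 1 or -1")
  if (!all(df$quality %in% c(1, 0))) stop(path, ": quality must be 1 or 0")
  if (anyDuplicated(df$record_id)) stop(path, ": duplicated record_id")
  df
}

#' @rdname read_labels
#' @param labels Data frame with columns `record_id`, `diagnosis`, `quality`.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels[c("record_id", "diagnosis", "quality")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write feature tables
#'
#' CSV with a `record_id` column followed by the 515 canonical feature
#' columns in the fixed order given by [pcg_feature_names()]. Values are
#' written with full double precision so a round trip is lossless to at
#' least 1e-12 relative.
#'
#' @param path CSV path.
#' @return Data frame: `record_id` plus 515 numeric columns.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  canonical <- pcg_feature_names()$name
  if (!identical(names(df), c("record_id", canonical))) {
    stop(path, ": columns do not match the canonical 515-feature schema")
  }
  df
}

#' @rdname read_feature_table
#' @param table Data frame as returned by [extract_feature_table()].
#' @export
write_feature_table <- function(table, path) {
  canonical <- pcg_feature_names()$name
  if (!identical(names(table), c("record_id", canonical))) {
    stop("feature table columns do not match the canonical schema")
  }
  out <- table
  for (j in seq_along(out)[-1]) {
    v <- sprintf("%.17g", out[[j]])
    v[!is.finite(out[[j]])] <- "NA"
    out[[j]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
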
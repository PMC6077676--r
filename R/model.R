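## SVM models for signal-quality estimation (labels 1/0) and normal/abnormal
## diagnosis (labels +1/-1), plus the uncertain-decision rule.
##
## The soft-margin dual is solved by e1071 (libsvm) for the Gaussian RBF
## kernel exp(-||xi-xj||^2 / (2 sigma^2)) and the linear kernel, and by
## kernlab for the non-squared exponential form exp(-||xi-xj|| / gamma)
## (Laplacian kernel), exposed because both parameterizations are current
## in the heart-sound literature. Columns are median-imputed and z-scored
## with statistics from the training split only: an RBF over raw
## heterogeneous units (seconds vs ratios vs spectrum magnitudes) would be
## dominated by scale.

#' Fit an SVM on a PCG feature table
#'
#' @param x Numeric matrix or data frame of features (rows = recordings).
#'   A `record_id` column, if present, is used for row names.
#' @param y Labels: two distinct values, e.g. +1/-1 (diagnosis) or 1/0
#'   (quality). The numerically larger value is the positive class (positive
#'   margin).
#' @param sigma RBF kernel width; the default 14 is the empirical optimum
#'   of the grid search over 4..35 on the CinC-2016 database.
#' @param C Soft-margin penalty factor.
#' @param kernel `"rbf"` (Gaussian, default), `"laplacian"` (non-squared
#'   exponential with scale `sigma`), or `"linear"`.
#' @param class_weighting `"none"` (default, plain SVM) or `"balanced"`
#'   (penalties inversely proportional to class frequency, for the heavily
#'   unbalanced quality labels).
#' @return An object of class `pcg_svm`.
#' @export
pcg_svm <- function(x, y, sigma = 14, C = 1,
                    kernel = c("rbf", "laplacian", "linear"),
                    class_weighting = c("none", "balanced")) {
  kernel <- match.arg(kernel)
  class_weighting <- match.arg(class_weighting)
  stopifnot(sigma > 0, C > 0)
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(x))
  classes <- sort(unique(y), decreasing = TRUE)
  if (length(classes) != 2) {
    stop("pcg_svm needs exactly two classes in y (got ",
         length(classes), ")")
  }
  yf <- factor(y, levels = classes) # positive class first

  ## column hygiene: drop all-missing columns, impute, standardize
  all_na <- colSums(is.finite(x)) == 0
  if (any(all_na)) {
    warning("dropping ", sum(all_na), " all-missing feature column(s): ",
            paste(utils::head(colnames(x)[all_na], 5), collapse = ", "))
    x <- x[, !all_na, drop = FALSE]
  }
  impute <- apply(x, 2, function(col) stats::median(col[is.finite(col)]))
  for (j in seq_len(ncol(x))) {
    x[!is.finite(x[, j]), j] <- impute[j]
  }
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[!is.finite(scale_) | scale_ == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")

  cw <- NULL
  if (class_weighting == "balanced") {
    tab <- table(yf)
    cw <- stats::setNames(as.numeric(sum(tab) / (2 * tab)), names(tab))
  }

  fit <- if (kernel == "laplacian") {
    kernlab::ksvm(xs, yf, kernel = kernlab::laplacedot(sigma = 1 / sigma),
                  C = C, scaled = FALSE,
                  class.weights = cw)
  } else {
    e1071::svm(xs, yf,
               kernel = if (kernel == "rbf") "radial" else "linear",
               gamma = 1 / (2 * sigma^2), cost = C, scale = FALSE,
               class.weights = cw)
  }

  structure(
    list(
      fit = fit, kernel = kernel, sigma = sigma, C = C,
      classes = classes, feature_names = colnames(x),
      impute = impute, center = center, scale = scale_,
      class_weighting = class_weighting
    ),
    class = "pcg_svm"
  )
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    if ("record_id" %in% names(x)) {
      rn <- x$record_id
      x <- x[setdiff(names(x), "record_id")]
      rownames(x) <- rn
    }
    x <- as.matrix(x)
  }
  storage.mode(x) <- "double"
  x
}

#' @export
print.pcg_svm <- function(x, ...) {
  cat(sprintf(
    "<pcg_svm> %s kernel (sigma = %g), C = %g; classes {%s}; %d features\n",
    x$kernel, x$sigma, x$C, paste(x$classes, collapse = ", "),
    length(x$feature_names)
  ))
  invisible(x)
}

#' Predict labels and margins from a fitted PCG SVM
#'
#' @param object A [pcg_svm].
#' @param newdata Feature matrix or data frame with (at least) the columns
#'   used at training time; extra columns are ignored, missing ones raise
#'   an error naming them.
#' @param ... Unused.
#' @return Data frame with columns `label` (the original class codes) and
#'   `margin` (signed decision value; positive = positive class).
#' @method predict pcg_svm
#' @export
predict.pcg_svm <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  miss <- setdiff(object$feature_names, colnames(x))
  if (length(miss)) {
    stop("newdata is missing feature column(s): ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5))
  }
  x <- x[, object$feature_names, drop = FALSE]
  for (j in seq_len(ncol(x))) {
    x[!is.finite(x[, j]), j] <- object$impute[j]
  }
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")

  if (object$kernel == "laplacian") {
    lab <- kernlab::predict(object$fit, xs)
    dv <- kernlab::predict(object$fit, xs, type = "decision")[, 1]
    ## kernlab's decision sign follows its internal level order; align it
    if (length(lab) && any(lab == levels(lab)[1])) {
      if (mean(dv[lab == levels(lab)[1]]) < 0) dv <- -dv
    }
  } else {
    p <- stats::predict(object$fit, xs, decision.values = TRUE)
    lab <- p
    dv <- attr(p, "decision.values")[, 1]
    ## e1071 names the column "<pos>/<neg>"; ensure positive margin = pos
    if (!identical(colnames(attr(p, "decision.values"))[1],
                   paste(object$classes, collapse = "/"))) {
      dv <- -dv
    }
  }
  data.frame(
    record_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    label = object$classes[as.integer(match(lab, levels(lab)))],
    margin = as.numeric(dv),
    row.names = NULL
  )
}

#' Classify recordings as normal / uncertain / abnormal
#'
#' Applies the quality model first, then the diagnosis model. A recording
#' is labeled 0 (uncertain) if and only if it is predicted noisy
#' (quality 0) and the absolute diagnosis margin is below `tau`;
#' `tau = 0` disables the uncertain class, `tau = Inf` sends every
#' predicted-noisy recording to uncertain.
#'
#' @param quality_model,diagnosis_model Fitted [pcg_svm] objects (quality:
#'   classes 1/0; diagnosis: classes +1/-1).
#' @param x Feature table for the recordings to classify.
#' @param tau Margin threshold of the uncertain rule.
#' @return Data frame with columns `record_id`, `label` (+1, 0, -1),
#'   `quality` (1/0), `margin`.
#' @export
classify_records <- function(quality_model, diagnosis_model, x, tau = 0.3) {
  stopifnot(tau >= 0)
  q <- predict(quality_model, x)
  d <- predict(diagnosis_model, x)
  label <- d$label
  uncertain <- q$label == 0 & abs(d$margin) < tau
  label[uncertain] <- 0
  data.frame(
    record_id = d$record_id,
    label = label,
    quality = q$label,
    margin = d$margin,
    row.names = NULL
  )
}

#' Select the k features most correlated with the label
#'
#' Ranks features by absolute Pearson correlation with the label on the
#' supplied (training) data and returns the top `k` names; ties are broken
#' by canonical column order.
#'
#' @param x Training feature table.
#' @param y Training labels.
#' @param k Number of features to keep, `1 <= k <= ncol`.
#' @return Character vector of `k` feature names.
#' @export
select_top_features <- function(x, y, k) {
  x <- as_feature_matrix(x)
  if (k < 1 || k > ncol(x)) {
    stop("k must be between 1 and ", ncol(x))
  }
  rk <- rank_features(x, y)
  rk$name[order(rk$rank)][seq_len(k)]
}
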
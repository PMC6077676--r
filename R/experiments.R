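## Evaluation protocols: repeated stratified random splits (with the
## degenerate train-on-all/test-on-all memorization case), k-fold
## cross-validation, and per-domain runs. Per-repeat seeds are derived
## from the master seed so any single repeat is reproducible in isolation.

fit_and_score <- function(x, labels, train_idx, test_idx, feature_subset,
                          sigma, C, kernel) {
  xm <- as_feature_matrix(x)
  if (!is.null(feature_subset)) {
    xm <- xm[, feature_subset, drop = FALSE]
  }
  model <- pcg_svm(xm[train_idx, , drop = FALSE],
                   labels$diagnosis[train_idx],
                   sigma = sigma, C = C, kernel = kernel)
  pred <- predict(model, xm[test_idx, , drop = FALSE])
  reference <- labels[test_idx, c("record_id", "diagnosis", "quality")]
  decisions <- data.frame(record_id = reference$record_id,
                          label = pred$label)
  score_decisions(reference, decisions)
}

summarize_scores <- function(scores, meta) {
  df <- data.frame(
    Se = vapply(scores, `[[`, numeric(1), "Se"),
    Sp = vapply(scores, `[[`, numeric(1), "Sp"),
    overall = vapply(scores, `[[`, numeric(1), "overall")
  )
  structure(
    list(
      runs = df,
      summary = data.frame(
        metric = c("Se", "Sp", "overall"),
        mean = vapply(df, mean, numeric(1)),
        sd = vapply(df, function(v) if (length(v) > 1) stats::sd(v) else NA_real_,
                    numeric(1)),
        row.names = NULL
      ),
      meta = meta
    ),
    class = "pcg_experiment"
  )
}

#' @export
print.pcg_experiment <- function(x, ...) {
  cat("<pcg_experiment>",
      paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-8s %s\n", s$metric[i],
                format_mean_sd(s$mean[i], s$sd[i])))
  }
  invisible(x)
}

#' Format a score as "mean+/-SD"
#'
#' @param mean,sd Numbers.
#' @param digits Decimal places.
#' @return Character scalar, e.g. `"0.88±0.02"`.
#' @export
format_mean_sd <- function(mean, sd, digits = 2) {
  if (is.na(sd)) return(sprintf("%.*f", digits, mean))
  sprintf("%.*f±%.*f", digits, mean, digits, sd)
}

#' Repeated stratified random-split evaluation
#'
#' For each repeat, `train_fraction` of the normal and of the abnormal
#' recordings are sampled (stratified by diagnosis, no overlap with the
#' test set), a diagnosis SVM is fitted, and the held-out recordings are
#' scored with weights from the test split's own reference labels.
#' `train_fraction = 1` is the memorization protocol: the model is trained
#' and tested on the full cohort.
#'
#' @param x Feature table (with `record_id` column or rownames).
#' @param labels Data frame with `record_id`, `diagnosis`, `quality`.
#' @param train_fraction Fraction of each class used for training
#'   (0 < f <= 1).
#' @param repeats Number of independent repeats (forced to 1 when
#'   `train_fraction = 1`).
#' @param feature_subset Optional character vector of feature names.
#' @param sigma,C,kernel Passed to [pcg_svm()].
#' @param seed Master seed.
#' @return A `pcg_experiment`: per-run scores plus a mean/SD summary.
#' @export
run_split_experiment <- function(x, labels, train_fraction = 0.1,
                                 repeats = 200, feature_subset = NULL,
                                 sigma = 14, C = 1, kernel = "rbf",
                                 seed = 1) {
  stopifnot(train_fraction > 0, train_fraction <= 1)
  n <- nrow(labels)
  if (train_fraction == 1) {
    scores <- list(fit_and_score(x, labels, seq_len(n), seq_len(n),
                                 feature_subset, sigma, C, kernel))
    return(summarize_scores(scores, list(protocol = "memorization",
                                         train_fraction = 1, repeats = 1)))
  }
  idx_by_class <- split(seq_len(n), labels$diagnosis)
  scores <- lapply(seq_len(repeats), function(r) {
    with_seed(derive_seed(seed, r), {
      repeat {
        train_idx <- sort(unlist(lapply(idx_by_class, function(idx) {
          sample(idx, max(1, round(train_fraction * length(idx))))
        })))
        test_idx <- setdiff(seq_len(n), train_idx)
        if (length(unique(labels$diagnosis[train_idx])) == 2 &&
            length(test_idx) > 0) break
        message("resampling split: train set had a single class")
      }
      fit_and_score(x, labels, train_idx, test_idx, feature_subset,
                    sigma, C, kernel)
    })
  })
  summarize_scores(scores, list(protocol = "split",
                                train_fraction = train_fraction,
                                repeats = repeats))
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by diagnosis; every recording is tested exactly
#' once and the pooled decisions are scored as one cohort.
#'
#' @inheritParams run_split_experiment
#' @param folds Number of folds.
#' @return A `pcg_score` for the pooled decisions, with attribute
#'   `fold_assignment`.
#' @export
run_cv_experiment <- function(x, labels, folds = 10, feature_subset = NULL,
                              sigma = 14, C = 1, kernel = "rbf", seed = 1) {
  n <- nrow(labels)
  fold_of <- integer(n)
  with_seed(seed, {
    for (idx in split(seq_len(n), labels$diagnosis)) {
      fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  xm <- as_feature_matrix(x)
  if (!is.null(feature_subset)) xm <- xm[, feature_subset, drop = FALSE]
  decisions <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    model <- pcg_svm(xm[train_idx, , drop = FALSE],
                     labels$diagnosis[train_idx], sigma = sigma, C = C,
                     kernel = kernel)
    pred <- predict(model, xm[test_idx, , drop = FALSE])
    decisions[[f]] <- data.frame(record_id = labels$record_id[test_idx],
                                 label = pred$label)
  }
  out <- score_decisions(labels, do.call(rbind, decisions))
  attr(out, "fold_assignment") <- fold_of
  out
}

#' Cross-validated evaluation restricted to one feature domain
#'
#' @inheritParams run_cv_experiment
#' @param domain One of the nine domain names (see [pcg_domain_counts()]).
#' @return A `pcg_score` as in [run_cv_experiment()].
#' @export
run_domain_experiment <- function(x, labels, domain, folds = 10,
                                  sigma = 14, C = 1, seed = 1) {
  schema <- pcg_feature_names()
  if (!domain %in% names(FEATURE_DOMAINS)) {
    stop("unknown domain '", domain, "'; expected one of: ",
         paste(names(FEATURE_DOMAINS), collapse = ", "))
  }
  run_cv_experiment(x, labels, folds = folds,
                    feature_subset = schema$name[schema$domain == domain],
                    sigma = sigma, C = C, seed = seed)
}
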
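## Challenge scoring: 12-cell confusion tally over reference categories
## (normal/abnormal x clean/noisy) vs decisions (normal/uncertain/abnormal),
## class-prevalence weights, and the modified sensitivity/specificity in
## which an uncertain decision counts as correct for noisy records only.

#' Tally decisions against reference labels
#'
#' @param reference Data frame with columns `record_id`, `diagnosis`
#'   (+1/-1), `quality` (1/0).
#' @param decisions Data frame with columns `record_id`, `label`
#'   (+1 abnormal, 0 uncertain, -1 normal), one row per reference record.
#' @return Named integer vector of class `pcg_confusion` with the 12 cells
#'   `Nn1, Nq1, Na1, Nn2, Nq2, Na2, An1, Aq1, Aa1, An2, Aq2, Aa2`
#'   (N/A = reference normal/abnormal; n/q/a = decided normal/uncertain/
#'   abnormal; 1 = clean, 2 = noisy).
#' @export
tally_decisions <- function(reference, decisions) {
  if (anyDuplicated(reference$record_id)) stop("duplicate reference record ids")
  if (anyDuplicated(decisions$record_id)) stop("duplicate decision record ids")
  missing_ids <- setdiff(reference$record_id, decisions$record_id)
  if (length(missing_ids)) {
    stop("no decision for record(s): ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  dec <- decisions$label[match(reference$record_id, decisions$record_id)]
  stopifnot(all(dec %in% c(-1, 0, 1)),
            all(reference$diagnosis %in% c(-1, 1)),
            all(reference$quality %in% c(0, 1)))

  cells <- c("Nn1", "Nq1", "Na1", "Nn2", "Nq2", "Na2",
             "An1", "Aq1", "Aa1", "An2", "Aq2", "Aa2")
  counts <- stats::setNames(integer(12), cells)
  ref_cls <- ifelse(reference$diagnosis == 1, "A", "N")
  noise <- ifelse(reference$quality == 1, "1", "2")
  dec_cls <- c("n", "q", "a")[dec + 2]
  key <- paste0(ref_cls, dec_cls, noise)
  tab <- table(key)
  counts[names(tab)] <- as.integer(tab)
  structure(counts, class = "pcg_confusion")
}

#' @export
print.pcg_confusion <- function(x, ...) {
  m <- matrix(unclass(x), 4, 3, byrow = TRUE,
              dimnames = list(
                c("Normal, clean", "Normal, noisy",
                  "Abnormal, clean", "Abnormal, noisy"),
                c("normal", "uncertain", "abnormal")
              ))
  print(m)
  invisible(x)
}

#' Category weights from a reference cohort
#'
#' wa1/wa2 are the clean/noisy shares of the abnormal records; wn1/wn2 the
#' clean/noisy shares of the normal records, so wa1 + wa2 = wn1 + wn2 = 1.
#'
#' @param reference Data frame with columns `diagnosis`, `quality`.
#' @return Named list `wa1, wa2, wn1, wn2`.
#' @export
compute_weights <- function(reference) {
  abn <- reference$diagnosis == 1
  if (!any(abn) || all(abn)) {
    stop("reference cohort needs at least one normal and one abnormal record")
  }
  clean <- reference$quality == 1
  list(
    wa1 = sum(abn & clean) / sum(abn),
    wa2 = sum(abn & !clean) / sum(abn),
    wn1 = sum(!abn & clean) / sum(!abn),
    wn2 = sum(!abn & !clean) / sum(!abn)
  )
}

#' Weighted sensitivity, specificity and overall score
#'
#' Se = wa1 * Aa1/(Aa1+Aq1+An1) + wa2 * (Aa2+Aq2)/(Aa2+Aq2+An2);
#' Sp = wn1 * Nn1/(Na1+Nq1+Nn1) + wn2 * (Nn2+Nq2)/(Na2+Nq2+Nn2);
#' overall = (Se + Sp)/2. Uncertain decisions count as correct for noisy
#' records and as errors for clean ones. A zero-denominator term
#' contributes 0 with a warning.
#'
#' @param counts A `pcg_confusion` from [tally_decisions()].
#' @param weights Weights from [compute_weights()].
#' @return List of class `pcg_score` with elements `Se`, `Sp`, `overall`,
#'   and the weights used.
#' @export
pcg_score <- function(counts, weights) {
  term <- function(num, den, what) {
    if (den == 0) {
      warning("empty category (", what, "): term contributes 0")
      return(0)
    }
    num / den
  }
  k <- unclass(counts)
  Se <- weights$wa1 * term(k[["Aa1"]], k[["Aa1"]] + k[["Aq1"]] + k[["An1"]],
                           "clean abnormal") +
    weights$wa2 * term(k[["Aa2"]] + k[["Aq2"]],
                       k[["Aa2"]] + k[["Aq2"]] + k[["An2"]], "noisy abnormal")
  Sp <- weights$wn1 * term(k[["Nn1"]], k[["Na1"]] + k[["Nq1"]] + k[["Nn1"]],
                           "clean normal") +
    weights$wn2 * term(k[["Nn2"]] + k[["Nq2"]],
                       k[["Na2"]] + k[["Nq2"]] + k[["Nn2"]], "noisy normal")
  structure(
    list(Se = Se, Sp = Sp, overall = (Se + Sp) / 2, weights = weights),
    class = "pcg_score"
  )
}

#' @export
print.pcg_score <- function(x, ...) {
  cat(sprintf("Se = %.4f, Sp = %.4f, overall = %.4f\n",
              x$Se, x$Sp, x$overall))
  invisible(x)
}

#' Score decisions against a reference in one call
#'
#' @inheritParams tally_decisions
#' @param weights Optional weights; default recomputed from `reference`.
#' @return A `pcg_score`.
#' @export
score_decisions <- function(reference, decisions, weights = NULL) {
  pcg_score(tally_decisions(reference, decisions),
            weights %||% compute_weights(reference))
}

#' Correlation ranking of features against the label
#'
#' Pearson (or Spearman) correlation of every feature column with the
#' diagnosis label, missing values excluded pairwise. Features are ranked
#' by decreasing absolute correlation; ties and undefined correlations
#' (constant columns) rank by canonical column order, undefined last.
#'
#' @param x Feature table.
#' @param y Labels (+1/-1).
#' @param method `"pearson"` or `"spearman"`.
#' @return Data frame of class `pcg_ranking`: `name`, `domain` (when the
#'   schema matches the canonical one), `cc`, `rank`.
#' @export
rank_features <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as_feature_matrix(x)
  if (nrow(x) < 3) stop("need at least 3 records to rank features")
  y <- as.numeric(y)
  cc <- apply(x, 2, function(col) {
    ok <- is.finite(col)
    if (sum(ok) < 3 || stats::sd(col[ok]) == 0) return(NA_real_)
    stats::cor(col[ok], y[ok], method = method)
  })
  ord <- order(-abs(cc), seq_along(cc), na.last = TRUE)
  rk <- integer(length(cc))
  rk[ord] <- seq_along(cc)
  schema <- pcg_feature_names()
  out <- data.frame(name = colnames(x), cc = cc, rank = rk,
                    row.names = NULL)
  if (identical(colnames(x), schema$name)) out$domain <- schema$domain
  class(out) <- c("pcg_ranking", "data.frame")
  out
}

#' Domain membership counts among the top-k ranked features
#'
#' @param ranking A `pcg_ranking` over the canonical schema.
#' @param ks Cut-offs.
#' @return Data frame: one row per domain, one column per cut-off, rows
#'   ordered by the lexicographic comparison of the count columns
#'   (top-10, then top-100, ...), largest first.
#' @export
domain_top_counts <- function(ranking, ks = c(10, 100, 200, 300)) {
  if (is.null(ranking$domain)) stop("ranking lacks domain information")
  domains <- names(FEATURE_DOMAINS)
  counts <- vapply(ks, function(k) {
    top <- ranking$domain[ranking$rank <= k]
    vapply(domains, function(d) sum(top == d), integer(1))
  }, integer(length(domains)))
  out <- data.frame(domain = domains, counts)
  names(out)[-1] <- paste0("top_", ks)
  out[do.call(order, c(lapply(out[-1], function(v) -v))), , drop = FALSE]
}
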
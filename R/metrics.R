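# Classification and virtual-screening metrics: confusion-table rates,
# ROC-AUC (Mann-Whitney), PRC-AUC (average precision) and enrichment
# factors.

#' Confusion counts for binary predictions
#'
#' @param labels true labels, coercible to 0/1.
#' @param predictions predicted labels, coercible to 0/1.
#' @return List of class `confusion_counts`: `n_tp`, `n_fp`, `n_tn`,
#'   `n_fn`.
#' @export
confusion_counts <- function(labels, predictions) {
  labels <- .as01(labels); predictions <- .as01(predictions)
  if (length(labels) == 0) stop("empty input")
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length")
  structure(list(n_tp = sum(labels == 1 & predictions == 1),
                 n_fp = sum(labels == 0 & predictions == 1),
                 n_tn = sum(labels == 0 & predictions == 0),
                 n_fn = sum(labels == 1 & predictions == 0)),
            class = "confusion_counts")
}

.as01 <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    x <- tolower(x)
    return(as.integer(x %in% c("1", "positive", "active", "true", "yes")))
  }
  if (!all(x %in% c(0, 1))) stop("labels must be binary (0/1)")
  as.integer(x)
}

#' Recall, precision, TPR, FPR and accuracy from confusion counts
#'
#' recall = TP/(TP+FN); precision = TP/(TP+FP); TPR = recall;
#' FPR = FP/(FP+TN); accuracy = (TP+TN)/total.  A zero denominator yields
#' `NA` with a warning rather than a silent 0.
#'
#' @param counts a [confusion_counts()] object.
#' @return Named numeric vector `recall`, `precision`, `tpr`, `fpr`,
#'   `accuracy`.
#' @export
basic_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe_div <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined: zero denominator"); NA_real_ }
    else num / den
  }
  with(counts, {
    recall <- safe_div(n_tp, n_tp + n_fn, "recall")
    precision <- safe_div(n_tp, n_tp + n_fp, "precision")
    fpr <- safe_div(n_fp, n_fp + n_tn, "fpr")
    total <- n_tp + n_fp + n_tn + n_fn
    c(recall = recall, precision = precision, tpr = recall, fpr = fpr,
      accuracy = (n_tp + n_tn) / total)
  })
}

#' Area under the ROC curve
#'
#' Computed via the Mann-Whitney identity: the probability that a random
#' positive outscores a random negative, with ties credited 1/2.
#'
#' @param scores numeric scores, higher = more likely positive.
#' @param labels binary labels; both classes must be present.
#' @return ROC-AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- .as01(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve points
#'
#' @param scores,labels as in [roc_auc()].
#' @return data frame `threshold`, `fpr`, `tpr`, one row per distinct
#'   score plus the endpoints, suitable for trapezoidal integration.
#' @export
roc_curve <- function(scores, labels) {
  labels <- .as01(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / np, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / nn, 0)
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise (right-continuous) average-precision summation: the mean of
#' precision-at-rank over the ranks of the positives, under a stable
#' descending sort of the scores.  Linear PR interpolation is avoided
#' since it over-estimates the curve.
#'
#' @param scores numeric scores, higher = more likely positive.
#' @param labels binary labels with at least one positive.
#' @return PRC-AUC in `(0, 1]`.
#' @export
prc_auc <- function(scores, labels) {
  labels <- .as01(labels)
  if (sum(labels == 1) == 0) stop("at least one positive required")
  ord <- order(-scores, seq_along(scores))  # stable
  y <- labels[ord]
  prec_at <- cumsum(y) / seq_along(y)
  mean(prec_at[y == 1])
}

#' Precision-recall curve points
#'
#' @param scores,labels as in [prc_auc()].
#' @return data frame `threshold`, `recall`, `precision` (rank-wise).
#' @export
pr_curve <- function(scores, labels) {
  labels <- .as01(labels)
  if (sum(labels == 1) == 0) stop("at least one positive required")
  ord <- order(-scores, seq_along(scores))
  y <- labels[ord]
  data.frame(threshold = scores[ord],
             recall = cumsum(y) / sum(y),
             precision = cumsum(y) / seq_along(y))
}

#' Enrichment factor of a ranked screening list
#'
#' Hit-rate-ratio convention (default): the active rate within the top
#' `ceiling(fraction * N)` molecules by descending score, divided by the
#' overall active rate.  The `"recall"` convention instead divides the
#' fraction of all actives retrieved by the size fraction of the top set.
#' Tied scores are broken by stable input order.
#'
#' @param scores numeric scores, higher = better.
#' @param labels binary activity labels with at least one positive.
#' @param fraction top fraction of the list, in `(0, 1]` (default 0.05).
#' @param method `"hit_rate"` or `"recall"`.
#' @return The enrichment factor (non-negative).
#' @export
enrichment_factor <- function(scores, labels, fraction = 0.05,
                              method = c("hit_rate", "recall")) {
  method <- match.arg(method)
  labels <- .as01(labels)
  n <- length(scores)
  if (n == 0 || length(labels) != n) stop("scores/labels length mismatch")
  n_act <- sum(labels == 1)
  if (n_act == 0) stop("at least one positive required")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  m <- ceiling(fraction * n)
  top <- order(-scores, seq_along(scores))[seq_len(m)]
  hits <- sum(labels[top] == 1)
  if (method == "hit_rate") (hits / m) / (n_act / n)
  else (hits / n_act) / (m / n)
}
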
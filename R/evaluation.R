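# ROC/PR evaluation. The ROC AUC is computed as the Mann-Whitney
# probability (fraction of positive/negative score pairs won, ties counted
# half), which equals the trapezoidal area under the ROC curve. The PR area
# uses the step-wise average-precision convention, sum over thresholds of
# (recall increment) x precision — not trapezoidal interpolation.

#' Coerce labels to 0/1 integers
#' @noRd
.check_labels <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("scores/labels length mismatch")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  labels
}

#' ROC AUC (Mann-Whitney probability)
#'
#' `(#{(pos, neg) pairs with score_pos > score_neg} + 0.5 * ties) /
#' (n_pos * n_neg)`, computed via midranks.
#'
#' @param scores Numeric classifier scores (higher = more ORI-like).
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- .check_labels(labels, scores)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' (fpr, tpr) at every distinct threshold, descending, starting at (0, 0)
#' and ending at (1, 1).
#' @inheritParams roc_auc
#' @return Data frame (threshold, fpr, tpr); the (0,0) anchor carries
#'   threshold `Inf`.
#' @export
roc_points <- function(scores, labels) {
  labels <- .check_labels(labels, scores)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last <- cumsum(rep(1, length(s)))[!duplicated(s, fromLast = TRUE)]
  thr <- s[!duplicated(s)]
  tp <- cumsum(l)[last]
  fp <- last - tp
  df <- data.frame(threshold = c(Inf, thr),
                   fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  rownames(df) <- NULL
  df
}

#' Precision-recall curve and average precision
#'
#' Precision and recall at every distinct threshold (descending); the area
#' is the step-wise sum `sum_i (R_i - R_{i-1}) * P_i` (average precision).
#'
#' @inheritParams roc_auc
#' @return List with `points` (data frame threshold, recall, precision) and
#'   `aupr`.
#' @export
pr_aupr <- function(scores, labels) {
  labels <- .check_labels(labels, scores)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0) stop("no positives")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last <- which(!duplicated(s, fromLast = TRUE))
  thr <- s[!duplicated(s)]
  tp <- cumsum(l)[last]
  n_at <- last
  recall <- tp / n_pos
  precision <- tp / n_at
  aupr <- sum(diff(c(0, recall)) * precision)
  list(points = data.frame(threshold = thr, recall = recall,
                           precision = precision),
       aupr = aupr)
}

#' PR baseline of a prevalence-rate random classifier
#'
#' The PR area of a classifier scoring at random equals the positive-class
#' fraction `n_pos / (n_pos + n_neg)`.
#'
#' @param n_pos,n_neg Class counts.
#' @return Fraction in `[0, 1]`.
#' @export
aupr_baseline <- function(n_pos, n_neg) {
  if (n_pos < 0 || n_neg < 0) stop("negative class count")
  if (n_pos + n_neg == 0) stop("both class counts are zero")
  n_pos / (n_pos + n_neg)
}

#' Recall of known positives at a probability cutoff
#'
#' A known positive is identified when its predicted probability strictly
#' exceeds the cutoff (a probability exactly at the cutoff is not counted).
#'
#' @param probabilities Predicted probabilities of known positives.
#' @param cutoff Decision cutoff (default 0.5).
#' @return List with `identified`, `total` and `percentage`
#'   (`100 * identified / total`, rounded to 2 decimal places).
#' @export
recall_at_cutoff <- function(probabilities, cutoff = 0.5) {
  total <- length(probabilities)
  if (total == 0) stop("no probabilities supplied")
  identified <- sum(probabilities > cutoff)
  list(identified = identified, total = total,
       percentage = round(100 * identified / total, 2))
}

#' Full evaluation of a score vector
#'
#' @inheritParams roc_auc
#' @return An object of class `EvalResult`: roc points, `auc`, pr points,
#'   `aupr`, `aupr_baseline`, `n_pos`, `n_neg`.
#' @export
evaluate_scores <- function(scores, labels) {
  labels <- .check_labels(labels, scores)
  pr <- pr_aupr(scores, labels)
  obj <- list(roc = roc_points(scores, labels),
              auc = roc_auc(scores, labels),
              pr = pr$points, aupr = pr$aupr,
              aupr_baseline = aupr_baseline(sum(labels == 1L), sum(labels == 0L)),
              n_pos = sum(labels == 1L), n_neg = sum(labels == 0L))
  class(obj) <- "EvalResult"
  obj
}

#' @export
print.EvalResult <- function(x, ...) {
  cat(sprintf(
    "EvalResult: %d pos / %d neg | AUC %.4f | AUPR %.4f (baseline %.4f)\n",
    x$n_pos, x$n_neg, x$auc, x$aupr, x$aupr_baseline))
  invisible(x)
}

#' Cross-cell-line AUC matrix
#'
#' Entry (i, j) is the AUC of model i evaluated on dataset j; the diagonal
#' is within-cell-line evaluation. All models must have been trained on the
#' same (shared) feature names.
#'
#' @param models Named list of `ForestModel` objects (one per cell line).
#' @param datasets Named list; each element a list with `fm` (a
#'   `FeatureMatrix`) and optional `rows` (evaluation row indices, default
#'   all).
#' @return Numeric matrix (models x datasets) of AUCs.
#' @export
cross_cell_matrix <- function(models, datasets) {
  out <- matrix(NA_real_, length(models), length(datasets),
                dimnames = list(names(models), names(datasets)))
  for (i in seq_along(models)) {
    for (j in seq_along(datasets)) {
      d <- datasets[[j]]
      rows <- if (is.null(d$rows)) seq_len(nrow(d$fm$X)) else d$rows
      p <- predict_proba(models[[i]], d$fm, rows)
      out[i, j] <- roc_auc(p, d$fm$labels[rows])
    }
  }
  out
}
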
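# Random-forest classification of ORI vs non-ORI regions. The ensemble is
# ranger with its defaults (500 trees, mtry = floor(sqrt(p)), unlimited
# depth, Gini splits), single-threaded with a fixed seed so results are
# reproducible. Variable importance is the permutation importance on the
# out-of-bag samples, i.e. the mean decrease in accuracy when a feature is
# permuted; the feature-elimination curve retrains on importance-ranked
# nested subsets and records the evaluation AUC at each size.

#' Train a random forest on a FeatureMatrix
#'
#' @param fm A `FeatureMatrix`.
#' @param rows Integer indices of training rows (default all).
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed; together with single-threaded growth this makes
#'   importances and predictions deterministic.
#' @param mtry Features tried per split; `NULL` uses `floor(sqrt(p))`.
#' @return An object of class `ForestModel`: the fitted ensemble plus
#'   `feature_names` (training order), `oob_importance` (named mean
#'   decrease in accuracy), `n_trees`, `seed`.
#' @export
train_forest <- function(fm, rows = NULL, n_trees = 500, seed = 1,
                         mtry = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(fm$X))
  X <- fm$X[rows, , drop = FALSE]
  y <- fm$labels[rows]
  if (anyNA(X)) stop("NaN/NA feature values in training rows")
  if (length(unique(y)) < 2) stop("training rows contain a single class")
  yf <- factor(y, levels = c(0L, 1L))
  fit <- ranger::ranger(
    x = as.data.frame(X, check.names = FALSE), y = yf,
    num.trees = n_trees, mtry = mtry,
    importance = "permutation",
    seed = seed, num.threads = 1
  )
  obj <- list(fit = fit,
              feature_names = colnames(X),
              oob_importance = fit$variable.importance,
              n_trees = n_trees, seed = seed,
              positive_level = "1")
  class(obj) <- "ForestModel"
  obj
}

#' @export
print.ForestModel <- function(x, ...) {
  cat(sprintf("ForestModel: %d trees, %d features, OOB error %.4f\n",
              x$n_trees, length(x$feature_names), x$fit$prediction.error))
  invisible(x)
}

#' Features ranked by OOB importance
#'
#' Stable ordering: importance descending, ties broken by name ascending,
#' so rankings are reproducible.
#' @param model A `ForestModel`.
#' @return Data frame (feature, importance, rank).
#' @export
importance_ranking <- function(model) {
  vi <- model$oob_importance
  ord <- order(-vi, names(vi), method = "radix")
  data.frame(feature = names(vi)[ord], importance = unname(vi[ord]),
             rank = seq_along(vi), stringsAsFactors = FALSE)
}

#' Predict ORI probabilities
#'
#' The probability is the fraction of trees voting for the positive class.
#' Columns are matched by name, so extra columns are ignored and column
#' order is irrelevant; a missing feature is an error naming the columns.
#'
#' @param model A `ForestModel`.
#' @param fm A `FeatureMatrix` (or bare numeric matrix with column names).
#' @param rows Integer indices of rows to score (default all).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, fm, rows = NULL) {
  X <- if (inherits(fm, "FeatureMatrix")) fm$X else fm
  if (is.null(rows)) rows <- seq_len(nrow(X))
  miss <- setdiff(model$feature_names, colnames(X))
  if (length(miss)) {
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  }
  X <- X[rows, model$feature_names, drop = FALSE]
  pred <- stats::predict(model$fit,
                         data = as.data.frame(X, check.names = FALSE),
                         predict.all = TRUE, num.threads = 1)$predictions
  pos <- which(model$fit$forest$levels == model$positive_level)
  rowMeans(pred == pos)
}

#' Importance-ranked feature-elimination curve
#'
#' Ranks features once by the OOB permutation importance of the full model,
#' then for each subset size in the grid retrains on the top-k subset and
#' records the AUC on the evaluation rows (the incremental-feature-selection
#' curve). `mode = "recursive"` instead re-ranks with the model of the
#' current subset before each elimination step; in both modes the subsets
#' are nested.
#'
#' @param fm A `FeatureMatrix`.
#' @param train_rows,eval_rows Integer row indices for training and
#'   evaluation.
#' @param size_grid Strictly decreasing subset sizes within `[1, p]`;
#'   `NULL` uses the default landmark grid
#'   p, 500, 400, 300, 200, 100, 80, 60, 40, 20, 10, 5, 2, 1 clipped to p.
#' @param n_trees,seed Passed to [train_forest()] for every refit.
#' @param mode `"rank_once"` (default) or `"recursive"`.
#' @return An object of class `RfeTrace`: `trace` data frame (size, auc),
#'   `subsets` (nested feature-name vectors), `best_size` (maximal AUC,
#'   ties resolved to the smallest size), `mode`.
#' @export
rfe_curve <- function(fm, train_rows, eval_rows, size_grid = NULL,
                      n_trees = 500, seed = 1,
                      mode = c("rank_once", "recursive")) {
  mode <- match.arg(mode)
  p <- ncol(fm$X)
  if (is.null(size_grid)) {
    size_grid <- sort(unique(pmin(
      c(p, 500, 400, 300, 200, 100, 80, 60, 40, 20, 10, 5, 2, 1), p)),
      decreasing = TRUE)
  }
  size_grid <- as.integer(size_grid)
  if (any(size_grid > p) || any(size_grid < 1)) {
    stop("size_grid must lie within [1, ", p, "]")
  }
  if (is.unsorted(rev(size_grid), strictly = TRUE)) {
    stop("size_grid must be strictly decreasing")
  }
  eval_labels <- fm$labels[eval_rows]
  full <- train_forest(fm, train_rows, n_trees = n_trees, seed = seed)
  ranking <- importance_ranking(full)$feature
  current <- colnames(fm$X)
  aucs <- numeric(length(size_grid))
  subsets <- vector("list", length(size_grid))
  for (i in seq_along(size_grid)) {
    k <- size_grid[i]
    keep <- if (mode == "rank_once") {
      ranking[seq_len(k)]
    } else {
      # re-rank within the surviving set, then trim
      rk <- if (length(current) == p) ranking else {
        m <- train_forest(subset_features(fm, current), train_rows,
                          n_trees = n_trees, seed = seed)
        importance_ranking(m)$feature
      }
      rk[seq_len(k)]
    }
    # original column order keeps refits reproducible and makes the
    # full-width point coincide with the full model
    keep <- colnames(fm$X)[colnames(fm$X) %in% keep]
    model <- if (k == p) full else {
      train_forest(subset_features(fm, keep), train_rows,
                   n_trees = n_trees, seed = seed)
    }
    aucs[i] <- roc_auc(predict_proba(model, fm, eval_rows), eval_labels)
    subsets[[i]] <- keep
    current <- keep
  }
  best <- min(size_grid[aucs == max(aucs)])
  obj <- list(trace = data.frame(size = size_grid, auc = aucs),
              subsets = subsets, best_size = best, mode = mode)
  class(obj) <- "RfeTrace"
  obj
}

#' @export
print.RfeTrace <- function(x, ...) {
  cat(sprintf("RfeTrace (%s): %d sizes, best_size %d (AUC %.4f)\n",
              x$mode, nrow(x$trace), x$best_size,
              max(x$trace$auc)))
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Feature subset selected at the best size of an RFE trace
#' @param trace An `RfeTrace`.
#' @return Character vector of feature names.
#' @export
best_features <- function(trace) {
  trace$subsets[[which(trace$trace$size == trace$best_size)]]
}

#' Shared features for cross-cell-line transfer
#'
#' Intersects a source model's features with the feature names available in
#' another cell line, preserving the source model's importance order, so a
#' model can be refit on exactly the shared marks.
#'
#' @param model_features Character vector of feature names in source
#'   importance order, or a `ForestModel` (its [importance_ranking()] order
#'   is used).
#' @param available Character vector of feature names available in the
#'   target cell line(s).
#' @return Character vector: the intersection in source order.
#' @export
transfer_features <- function(model_features, available) {
  if (inherits(model_features, "ForestModel")) {
    model_features <- importance_ranking(model_features)$feature
  }
  shared <- model_features[model_features %in% available]
  if (length(shared) == 0) stop("empty intersection of feature names")
  shared
}

#' Write an importance table (name, block, score, rank) as TSV
#' @param model A `ForestModel`.
#' @param fm The `FeatureMatrix` it was trained on (for the block index).
#' @param path Output path.
#' @return The table, invisibly.
#' @export
write_importance_tsv <- function(model, fm, path) {
  rk <- importance_ranking(model)
  block_of <- rep(names(fm$blocks), lengths(fm$blocks))
  names(block_of) <- unlist(fm$blocks)
  rk$block <- unname(block_of[rk$feature])
  rk <- rk[, c("feature", "block", "importance", "rank")]
  write.table(rk, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rk)
}
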
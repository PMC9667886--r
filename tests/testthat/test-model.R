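test_that("pure-noise features give chance-level tune AUC", {
  for (seed in 1:3) {
    pl <- withr::with_seed(seed, {
      list(X = matrix(runif(800 * 10), 800, 10),
           labels = rep(c(1L, 0L), each = 400))
    })
    fm <- make_fm(pl$X, pl$labels)
    train <- c(1:200, 401:600)
    tune <- c(201:400, 601:800)
    model <- train_forest(fm, train, n_trees = 200, seed = seed)
    auc <- roc_auc(predict_proba(model, fm, tune), fm$labels[tune])
    expect_gte(auc, 0.4)
    expect_lte(auc, 0.6)
  }
})

test_that("a perfectly separating feature gives AUC 1 and tops the ranking", {
  withr::local_seed(2)
  X <- matrix(runif(200 * 5), 200, 5)
  labels <- rep(c(1L, 0L), each = 100)
  X[, 3] <- labels + runif(200, 0, 0.1)
  fm <- make_fm(X, labels)
  train <- c(1:70, 101:170)
  tune <- c(71:100, 171:200)
  model <- train_forest(fm, train, seed = 2)
  expect_equal(roc_auc(predict_proba(model, fm, tune), fm$labels[tune]), 1)
  expect_equal(importance_ranking(model)$feature[1], "epi:f03")
})

test_that("planted informative features out-rank decoys in importance", {
  for (seed in 1:5) {
    pl <- planted_matrix(n = 300, n_inf = 5, n_dec = 45, seed = seed)
    fm <- make_fm(pl$X, pl$labels)
    model <- train_forest(fm, n_trees = 300, seed = seed)
    vi <- model$oob_importance
    inf_cols <- paste0("epi:f", sprintf("%02d", 1:5))
    expect_gt(mean(vi[inf_cols]), mean(vi[setdiff(names(vi), inf_cols)]))
  }
})

test_that("training rejects single-class rows and missing values", {
  pl <- planted_matrix(n = 60, n_inf = 2, n_dec = 3, seed = 1)
  fm <- make_fm(pl$X, pl$labels)
  expect_error(train_forest(fm, rows = 1:30, seed = 1), "single class")
  fm$X[1, 1] <- NA
  expect_error(train_forest(fm, seed = 1), "NaN/NA")
})

test_that("prediction is name-matched: column order and extras are ignored", {
  pl <- planted_matrix(n = 200, n_inf = 3, n_dec = 7, seed = 6)
  fm <- make_fm(pl$X, pl$labels)
  model <- train_forest(fm, seed = 6)
  p0 <- predict_proba(model, fm)
  # permuted columns
  perm <- fm$X[, sample(ncol(fm$X)), drop = FALSE]
  expect_equal(predict_proba(model, perm), p0)
  # extra column ignored
  extra <- cbind(fm$X, `epi:extra` = runif(nrow(fm$X)))
  expect_equal(predict_proba(model, extra), p0)
  # duplicate row scores identically
  dup <- fm$X[c(1, 1), , drop = FALSE]
  pd <- predict_proba(model, dup)
  expect_equal(pd[1], pd[2])
  # missing column is an error naming the feature
  expect_error(predict_proba(model, fm$X[, -2, drop = FALSE]), "epi:f02")
  # train rows are memorised by the ensemble
  expect_gt(roc_auc(p0, fm$labels), 0.95)
})

test_that("identical data and seed give identical importances and predictions", {
  pl <- planted_matrix(n = 150, n_inf = 2, n_dec = 8, seed = 3)
  fm <- make_fm(pl$X, pl$labels)
  m1 <- train_forest(fm, n_trees = 100, seed = 42)
  m2 <- train_forest(fm, n_trees = 100, seed = 42)
  expect_identical(m1$oob_importance, m2$oob_importance)
  expect_identical(predict_proba(m1, fm), predict_proba(m2, fm))
})

test_that("a constant column has near-zero importance", {
  for (seed in 1:5) {
    pl <- planted_matrix(n = 200, n_inf = 3, n_dec = 6, seed = seed)
    X <- cbind(pl$X, 0.5)
    fm <- make_fm(X, pl$labels)
    model <- train_forest(fm, n_trees = 200, seed = seed)
    expect_lt(abs(model$oob_importance[["epi:f10"]]), 0.005)
  }
})

test_that("rfe with a single full-width grid point equals the full model", {
  pl <- planted_matrix(n = 200, n_inf = 3, n_dec = 7, seed = 9)
  fm <- make_fm(pl$X, pl$labels)
  train <- c(1:70, 101:170)
  tune <- c(71:100, 171:200)
  trace <- rfe_curve(fm, train, tune, size_grid = 10, seed = 9)
  model <- train_forest(fm, train, seed = 9)
  expect_equal(trace$trace$auc,
               roc_auc(predict_proba(model, fm, tune), fm$labels[tune]))
  expect_error(rfe_curve(fm, train, tune, size_grid = c(11, 5), seed = 1),
               "within")
  expect_error(rfe_curve(fm, train, tune, size_grid = c(5, 5), seed = 1),
               "decreasing")
})

test_that("rfe subsets are nested and recover the planted features", {
  pl <- planted_matrix(n = 400, n_inf = 5, n_dec = 45, seed = 13)
  fm <- make_fm(pl$X, pl$labels)
  train <- c(1:150, 201:350)
  tune <- c(151:200, 351:400)
  trace <- rfe_curve(fm, train, tune, size_grid = c(50, 20, 10, 5, 2, 1),
                     n_trees = 300, seed = 13)
  for (i in 2:length(trace$subsets)) {
    expect_true(all(trace$subsets[[i]] %in% trace$subsets[[i - 1]]))
  }
  top5 <- trace$subsets[[which(trace$trace$size == 5)]]
  inf_cols <- paste0("epi:f", sprintf("%02d", 1:5))
  expect_gte(length(intersect(top5, inf_cols)), 4)
  k5 <- trace$trace$auc[trace$trace$size == 5]
  k1 <- trace$trace$auc[trace$trace$size == 1]
  expect_gte(k5, k1)
  # recursive mode also yields nested subsets
  tr2 <- rfe_curve(fm, train, tune, size_grid = c(50, 10, 2),
                   n_trees = 100, seed = 13, mode = "recursive")
  expect_true(all(tr2$subsets[[3]] %in% tr2$subsets[[2]]))
  expect_true(all(tr2$subsets[[2]] %in% tr2$subsets[[1]]))
})

test_that("transfer_features intersects in source importance order", {
  expect_equal(transfer_features(c("a", "b", "c"), c("a", "b", "c")),
               c("a", "b", "c"))
  expect_equal(transfer_features(c("a", "b", "c"), c("d", "c", "b")),
               c("b", "c"))
  expect_error(transfer_features(c("a", "b"), c("x", "y")),
               "empty intersection")
  src <- paste0("f", 1:60)
  avail <- paste0("f", seq(2, 78, by = 2))
  expect_length(transfer_features(src, avail), 30)
})
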
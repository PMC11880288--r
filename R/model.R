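# Random-forest regression wrapper exposing the four tunable
# hyperparameters (Ntrees, mTrees, MinLeafSize, Nsplits), plus the three
# evaluation metrics (RMSE, R^2, calibration slope).
#
# Nsplits is a per-tree split cap; in the binary-tree equivalence a tree
# with s splits has s + 1 leaves, so it maps onto randomForest's `maxnodes`
# (maximum number of terminal nodes) as maxnodes = n_splits + 1.

#' Random-forest configuration
#'
#' @param n_trees Number of trees in the forest.
#' @param m_trees Predictors sampled at each split (clipped to the number of
#'   selected features at fit time).
#' @param min_leaf_size Minimum observations per leaf.
#' @param n_splits Maximum splits per tree; `Inf` (the default) grows trees
#'   to the depth the leaf-size rule allows.
#' @param seed Integer seed for the forest's bootstrap/feature sampling.
#' @return A list of class `rfr_config`.
#' @export
rfr_config <- function(n_trees = 500L, m_trees = 4L, min_leaf_size = 5L,
                       n_splits = Inf, seed = 1L) {
  if (n_trees < 1 || m_trees < 1 || min_leaf_size < 1 || n_splits < 1) {
    abort("all hyperparameters must be >= 1")
  }
  structure(
    list(n_trees = as.integer(n_trees), m_trees = as.integer(m_trees),
         min_leaf_size = as.integer(min_leaf_size), n_splits = n_splits,
         seed = as.integer(seed)),
    class = "rfr_config"
  )
}

#' Default random-forest configuration
#'
#' The conventional defaults: 500 trees, predictors per split = one third of
#' the 12 inputs (= 4), minimum leaf size 5, and no split cap.
#'
#' @param seed Integer seed.
#' @return An [rfr_config()].
#' @export
rfr_default_config <- function(seed = 1L) {
  rfr_config(n_trees = 500L, m_trees = ceiling(12 / 3), min_leaf_size = 5L,
             n_splits = Inf, seed = seed)
}

#' Train a random-forest torque model on masked features
#'
#' @param table Feature table (12 features + `Torque`).
#' @param mask Logical vector of length 12 (or a character vector of feature
#'   names) selecting the features the forest may use.
#' @param cfg An [rfr_config()].
#' @return A fitted model of class `rfr_fit`.
#' @export
rfr_train <- function(table, mask = rep(TRUE, 12), cfg = rfr_default_config()) {
  if (is.character(mask)) mask <- MMG_FEATURES %in% mask
  if (!any(mask)) abort("mask selects no features")
  if (nrow(table) < 2) abort("need at least 2 rows")
  feats <- MMG_FEATURES[mask]
  x <- as.data.frame(table[feats])
  y <- table$Torque
  mtry <- min(cfg$m_trees, length(feats))
  maxnodes <- if (is.finite(cfg$n_splits)) {
    min(cfg$n_splits + 1, max(2, floor(nrow(table) / max(1, cfg$min_leaf_size))))
  } else {
    NULL
  }
  fit <- withr::with_seed(cfg$seed, suppressWarnings(
    randomForest::randomForest(
      x = x, y = y, ntree = cfg$n_trees, mtry = mtry,
      nodesize = cfg$min_leaf_size, maxnodes = maxnodes
    )
  ))
  structure(list(forest = fit, features = feats, config = cfg),
            class = "rfr_fit")
}

#' @export
print.rfr_fit <- function(x, ...) {
  cat(sprintf(
    "<rfr_fit> %d trees, mtry %d, min leaf %d, %s; features: %s\n",
    x$config$n_trees, min(x$config$m_trees, length(x$features)),
    x$config$min_leaf_size,
    if (is.finite(x$config$n_splits)) paste0("<= ", x$config$n_splits, " splits")
    else "unlimited splits",
    paste(x$features, collapse = ", ")
  ))
  invisible(x)
}

#' @export
predict.rfr_fit <- function(object, newdata, ...) {
  unname(predict(object$forest, as.data.frame(newdata[object$features])))
}

#' Regression metrics: RMSE, R-squared, calibration slope
#'
#' `metric_rmse()` is `sqrt(mean((y - yhat)^2))`; `metric_r2()` is
#' `1 - SS_res / SS_tot`; `metric_slope()` is the ordinary-least-squares
#' slope of predicted regressed on measured — 1 for unbiased calibration,
#' below 1 for compression towards the mean.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return A scalar.
#' @export
metric_rmse <- function(y, yhat) sqrt(mean((y - yhat)^2))

#' @rdname metric_rmse
#' @export
metric_r2 <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) abort("degenerate target: zero variance")
  1 - sum((y - yhat)^2) / sst
}

#' @rdname metric_rmse
#' @export
metric_slope <- function(y, yhat) {
  vy <- sum((y - mean(y))^2)
  if (vy <= 0) abort("degenerate target: zero variance")
  sum((y - mean(y)) * (yhat - mean(yhat))) / vy
}

#' Evaluate a fitted model on a row subset
#'
#' @param fit An `rfr_fit`.
#' @param table Feature table.
#' @param rows Integer row indices to evaluate on (default: all rows).
#' @return A one-row tibble with `rmse`, `r2`, `slope`, `n`.
#' @export
rfr_evaluate <- function(fit, table, rows = seq_len(nrow(table))) {
  sub <- table[rows, , drop = FALSE]
  yhat <- predict(fit, sub)
  tibble::tibble(
    rmse = metric_rmse(sub$Torque, yhat),
    r2 = metric_r2(sub$Torque, yhat),
    slope = metric_slope(sub$Torque, yhat),
    n = nrow(sub)
  )
}
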
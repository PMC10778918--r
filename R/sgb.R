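# Stochastic gradient boosting base model.
#
# The classifier is an additive ensemble of shallow trees,
# f(x) = sum_t a_t h_t(x), fit stagewise so each new tree targets the
# residual error of the existing ensemble; stochasticity enters through
# row subsampling (sample_size) and per-split predictor subsampling
# (mtry). xgboost provides the fitting engine.

#' Stochastic gradient boosting parameters
#'
#' The six tuned parameters of the boosting model plus the ensemble size.
#'
#' @param tree_depth maximum depth of each tree (default 3).
#' @param min_n minimum sum of instance weight in a child node
#'   (default 5).
#' @param loss_reduction minimum loss reduction required to make a split
#'   (default 0).
#' @param sample_size row subsampling fraction per tree, in (0, 1\]
#'   (default 0.8).
#' @param mtry number of predictors sampled per split; `NULL` means all.
#' @param learn_rate shrinkage applied to each tree's contribution, in
#'   (0, 1\] (default 0.1).
#' @param n_trees number of boosting iterations (default 150).
#' @return A validated list of class `"sgb_params"`.
#' @export
sgb_params <- function(tree_depth = 3, min_n = 5, loss_reduction = 0,
                       sample_size = 0.8, mtry = NULL, learn_rate = 0.1,
                       n_trees = 150) {
  p <- list(tree_depth = tree_depth, min_n = min_n,
            loss_reduction = loss_reduction, sample_size = sample_size,
            mtry = mtry, learn_rate = learn_rate, n_trees = n_trees)
  for (f in c("tree_depth", "min_n", "n_trees")) {
    if (!is.numeric(p[[f]]) || p[[f]] < 1) {
      stop(sprintf("`%s` must be a positive integer", f), call. = FALSE)
    }
  }
  if (p$loss_reduction < 0) stop("`loss_reduction` must be >= 0", call. = FALSE)
  for (f in c("sample_size", "learn_rate")) {
    if (!is.numeric(p[[f]]) || p[[f]] <= 0 || p[[f]] > 1) {
      stop(sprintf("`%s` must lie in (0, 1]", f), call. = FALSE)
    }
  }
  if (!is.null(p$mtry) && (!is.numeric(p$mtry) || p$mtry < 1)) {
    stop("`mtry` must be NULL or a positive integer", call. = FALSE)
  }
  class(p) <- "sgb_params"
  p
}

#' Fit the boosting classifier
#'
#' Fits a stochastic-gradient-boosted tree ensemble predicting cancer vs
#' normal status from the feature columns of a marker matrix (binary
#' markers plus any engineered features present).
#'
#' @param x a [marker_matrix] of training samples containing both classes.
#' @param params an [sgb_params] object.
#' @param seed RNG seed for the stochastic subsampling; fits are
#'   reproducible given the seed.
#' @return An object of class `"sgb_fit"` with a [predict.sgb_fit] method
#'   emitting P(cancer).
#' @export
fit_sgb <- function(x, params = sgb_params(), seed = 1) {
  feats <- feature_columns(x)
  y <- as.integer(x$status == "cancer")
  if (length(unique(y)) < 2L) {
    stop("training labels must contain both cancer and normal samples",
         call. = FALSE)
  }
  mtry <- params$mtry %||% length(feats)
  mtry <- min(mtry, length(feats))
  xm <- as.matrix(x[, feats, drop = FALSE])
  storage.mode(xm) <- "double"
  booster <- xgboost::xgb.train(
    params = xgboost::xgb.params(
      objective = "binary:logistic",
      max_depth = as.integer(params$tree_depth),
      min_child_weight = params$min_n,
      min_split_loss = params$loss_reduction,
      subsample = params$sample_size,
      colsample_bynode = mtry / length(feats),
      learning_rate = params$learn_rate,
      nthread = 1,
      seed = as.integer(seed) %% .Machine$integer.max
    ),
    data = xgboost::xgb.DMatrix(xm, label = y, nthread = 1),
    nrounds = as.integer(params$n_trees),
    verbose = 0
  )
  structure(list(booster = booster, features = feats, params = params,
                 seed = seed),
            class = "sgb_fit")
}

#' @describeIn fit_sgb predicted probability of cancer for new samples.
#' @param object a fitted `"sgb_fit"`.
#' @param newdata a [marker_matrix] or data frame carrying the fit's
#'   feature columns.
#' @param ... unused.
#' @export
predict.sgb_fit <- function(object, newdata, ...) {
  xm <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  storage.mode(xm) <- "double"
  stats::predict(object$booster, xm)
}

#' @export
print.sgb_fit <- function(x, ...) {
  cat(sprintf(
    "Stochastic gradient boosting fit: %d trees, depth %d, learn rate %g\n",
    x$params$n_trees, x$params$tree_depth, x$params$learn_rate))
  cat(sprintf("  features (%d): %s\n", length(x$features),
              paste(utils::head(x$features, 8), collapse = ", ")))
  invisible(x)
}

#' Tune the boosting parameters by cross-validated AUC
#'
#' Evaluates a grid of candidate parameter settings by stratified K-fold
#' cross-validation on the training set (leave-one-out available with
#' `cv_folds = "loo"`, where the AUC is computed on the pooled held-out
#' predictions) and returns the setting with the highest mean CV AUC.
#' Ties are broken in favour of the simpler model: smaller `tree_depth`,
#' then lower `learn_rate`.
#'
#' @param x a [marker_matrix] of training samples.
#' @param grid data frame of candidate settings (columns named as
#'   [sgb_params] arguments); `NULL` draws a random-search grid of
#'   `n_iter` settings.
#' @param n_iter random-search size when `grid` is `NULL` (default 25).
#' @param cv_folds number of folds (default 5) or `"loo"`.
#' @param seed RNG seed governing the grid draw and fold assignment.
#' @return The selected [sgb_params]; the evaluated grid with its CV AUCs
#'   is attached as attribute `"grid"`.
#' @export
tune_sgb <- function(x, grid = NULL, n_iter = 25, cv_folds = 5, seed = 1) {
  set.seed(seed)
  p <- length(feature_columns(x))
  if (is.null(grid)) {
    grid <- data.frame(
      tree_depth = sample(1:6, n_iter, replace = TRUE),
      min_n = sample(c(2, 5, 10, 20), n_iter, replace = TRUE),
      loss_reduction = sample(c(0, 0.01, 0.1, 1), n_iter, replace = TRUE),
      sample_size = stats::runif(n_iter, 0.5, 1),
      mtry = sample(seq_len(p), n_iter, replace = TRUE),
      learn_rate = 10^stats::runif(n_iter, -2, -0.5)
    )
  }
  if (nrow(grid) == 0L) stop("empty tuning grid", call. = FALSE)

  y <- x$status
  folds <- make_folds(y, cv_folds)
  auc_of <- function(row) {
    params <- do.call(sgb_params, as.list(row))
    held_scores <- rep(NA_real_, nrow(x))
    fold_aucs <- numeric(0)
    for (f in unique(folds)) {
      hold <- which(folds == f)
      fit <- fit_sgb(x[-hold, , drop = FALSE], params, seed = seed)
      held_scores[hold] <- predict(fit, x[hold, , drop = FALSE])
      if (length(unique(y[hold])) == 2L) {
        fold_aucs <- c(fold_aucs, roc_auc(held_scores[hold], y[hold])$auc)
      }
    }
    if (length(fold_aucs) > 0L) mean(fold_aucs)
    else roc_auc(held_scores, y)$auc  # pooled (leave-one-out)
  }
  grid$cv_auc <- vapply(seq_len(nrow(grid)),
                        function(i) auc_of(grid[i, setdiff(names(grid),
                                                           "cv_auc")]),
                        numeric(1))
  ord <- order(-grid$cv_auc, grid$tree_depth, grid$learn_rate)
  best <- grid[ord[1], ]
  out <- do.call(sgb_params,
                 as.list(best[setdiff(names(best), "cv_auc")]))
  attr(out, "grid") <- grid
  out
}

# stratified fold assignment; cv_folds = "loo" gives one fold per sample
make_folds <- function(y, cv_folds) {
  n <- length(y)
  if (identical(cv_folds, "loo")) return(seq_len(n))
  folds <- integer(n)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(cv_folds), length(idx))
  }
  folds
}
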
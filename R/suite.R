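# The staged model suite: base boosting model, three enhancement stages,
# importance-based marker selection, and the stacked one-class ensemble,
# all evaluated over the same plan of repeated train/test splits.

MSA_MODELS <- c("base", "M1_count", "M2_outlier", "M3_upsample", "M4_topk",
                "stacked")

#' Fit and evaluate the staged MSA model suite
#'
#' The central fitting function of the package. Runs, over a common plan
#' of repeated stratified train/test splits, a sequence of cumulative
#' modelling stages on a binary marker matrix:
#' \describe{
#'   \item{base}{stochastic gradient boosting on the binary markers only.}
#'   \item{M1_count}{adds the engineered marker-burden feature
#'     (`marker_count`).}
#'   \item{M2_outlier}{additionally removes random-forest proximity
#'     outliers (by default from the training fold only).}
#'   \item{M3_upsample}{additionally up-samples the minority class of the
#'     training fold to parity.}
#'   \item{M4_topk}{additionally restricts to the `top_k` markers ranked
#'     by permutation importance (importance measured on the training
#'     fold).}
#'   \item{stacked}{on the M4 feature set, a two-layer stack: out-of-fold
#'     boosting probability plus cancer/normal one-class SVM scores,
#'     combined by elastic-net logistic regression.}
#' }
#' Every stage's transformations are computed from the training fold
#' alone; the test fold is only ever scored.
#'
#' @param x a [marker_matrix].
#' @param plan a [split_plan] (default: 20 splits at 80/20).
#' @param models which stages to run (default all six, in order).
#' @param params [sgb_params] used for every boosting fit when
#'   `tune = FALSE`.
#' @param tune tune the boosting parameters by cross-validated random
#'   search within each training fold (default `FALSE`: use `params`
#'   as-is).
#' @param tune_iter random-search size when tuning (default 10).
#' @param top_k markers kept by the selection stage (default 8).
#' @param importance_K permutation repetitions per feature for the
#'   selection stage (default 200; the importance expectation does not
#'   depend on K).
#' @param outlier_sd SD threshold of the proximity outlier rule
#'   (default 1).
#' @param outlier_scope `"train"` (default, leakage-safe) removes
#'   outliers from the training fold of each split and leaves every test
#'   fold intact; `"all"` removes them once from the whole cohort before
#'   splitting, so stages from `M2_outlier` on are split and scored on
#'   the reduced cohort, which itself becomes the object of study.
#'   The `"all"` scope lets information from the removal step reach the
#'   test folds and should be read as replication, not validation.
#' @param nu one-class SVM nu for the stacked stage (default 0.1).
#' @param threshold probability threshold for the confusion metrics
#'   (default 0.5).
#' @return An object of class `"msa_suite"`: list with `results` (one row
#'   per model x split: accuracy, sensitivity, specificity, auc),
#'   `summary` (per-model means and SDs across splits), `importance`
#'   (per-split-averaged marker importance from the selection stage),
#'   `removed_outliers`, `predictions` (per-split test scores), `plan`
#'   and the configuration.
#' @examples
#' \donttest{
#' mm <- generate_marker_matrix(cohort_spec(n_cancer = 90, n_normal = 30,
#'                                          seed = 1))$matrix
#' fit <- msa_suite(mm, split_plan(n_splits = 2, master_seed = 1),
#'                  models = c("base", "M1_count"))
#' summary(fit)
#' }
#' @export
msa_suite <- function(x, plan = split_plan(n_splits = 20),
                      models = MSA_MODELS,
                      params = sgb_params(), tune = FALSE, tune_iter = 10,
                      top_k = 8, importance_K = 200,
                      outlier_sd = 1, outlier_scope = c("train", "all"),
                      nu = 0.1, threshold = 0.5) {
  stopifnot(inherits(x, "marker_matrix"))
  outlier_scope <- match.arg(outlier_scope)
  models <- match.arg(models, MSA_MODELS, several.ok = TRUE)
  x <- x[, c("sample_id", "status", marker_columns(x)), drop = FALSE]
  x <- marker_matrix(x)  # engineered columns are rebuilt stage by stage

  # With outlier_scope = "all" the proximity outliers leave the cohort
  # before any splitting, so the reduced cohort itself becomes the object
  # of study: the later stages are then split and scored on it. The
  # default "train" scope instead removes outliers from each
  # training fold only and never alters a test fold.
  whole_removed <- character(0)
  x_reduced <- NULL
  splits_reduced <- NULL
  if (outlier_scope == "all" &&
      any(models %in% c("M2_outlier", "M3_upsample", "M4_topk", "stacked"))) {
    om <- remove_outliers_rf(add_marker_count(x), sd_threshold = outlier_sd,
                             seed = plan$seeds[1])
    whole_removed <- om$removed
    x_reduced <- marker_matrix(
      as.data.frame(om$matrix)[, c("sample_id", "status",
                                   marker_columns(x)), drop = FALSE])
    splits_reduced <- split_data(x_reduced, plan)
  }

  splits <- split_data(x, plan)
  results <- list()
  predictions <- list()
  removed <- list()
  importances <- list()

  for (si in seq_along(splits)) {
    sp <- splits[[si]]
    seed <- sp$seed
    test_all <- x[sp$test, , drop = FALSE]

    needs_outliers <- any(models %in% c("M2_outlier", "M3_upsample",
                                        "M4_topk", "stacked"))
    # stage-shared training sets (cumulative transformations)
    train_m1 <- add_marker_count(marker_matrix(x[sp$train, , drop = FALSE]))
    test_m1 <- add_marker_count(marker_matrix(test_all))

    test_m2 <- test_m1
    if (needs_outliers) {
      if (outlier_scope == "all") {
        spr <- splits_reduced[[si]]
        train_m2 <- add_marker_count(marker_matrix(
          x_reduced[spr$train, , drop = FALSE]))
        test_m2 <- add_marker_count(marker_matrix(
          x_reduced[spr$test, , drop = FALSE]))
      } else {
        om <- remove_outliers_rf(train_m1, sd_threshold = outlier_sd,
                                 seed = seed)
        train_m2 <- om$matrix
        removed[[si]] <- om$removed
      }
      train_m3 <- upsample_minority(train_m2, seed = seed)
    }

    stage_params <- if (tune) {
      tune_sgb(train_m1, n_iter = tune_iter, seed = seed)
    } else {
      params
    }

    run_stage <- function(model, train, test) {
      fit <- if (model == "stacked") {
        fit_stacked(train, stage_params, nu = nu, seed = seed)
      } else {
        fit_sgb(train, stage_params, seed = seed)
      }
      scores <- predict(fit, test)
      cm <- confusion_metrics(scores, test$status, threshold = threshold)
      results[[length(results) + 1L]] <<- data.frame(
        model = model, seed = seed,
        accuracy = cm[["accuracy"]], sensitivity = cm[["sensitivity"]],
        specificity = cm[["specificity"]],
        auc = roc_auc(scores, test$status)$auc,
        n_train = nrow(train), n_test = nrow(test),
        stringsAsFactors = FALSE)
      predictions[[length(predictions) + 1L]] <<- data.frame(
        model = model, seed = seed, sample_id = test$sample_id,
        status = test$status, score = scores, stringsAsFactors = FALSE)
    }

    base_train <- marker_matrix(x[sp$train, , drop = FALSE])
    if ("base" %in% models) run_stage("base", base_train, test_all)
    if ("M1_count" %in% models) run_stage("M1_count", train_m1, test_m1)
    if ("M2_outlier" %in% models) run_stage("M2_outlier", train_m2, test_m2)
    if ("M3_upsample" %in% models) run_stage("M3_upsample", train_m3, test_m2)

    if (any(c("M4_topk", "stacked") %in% models)) {
      # rank markers from a fit on the markers alone: with marker_count in
      # the model the aggregate absorbs the signal and per-marker
      # importances collapse towards zero
      sel_train <- marker_matrix(
        train_m3[, setdiff(names(train_m3), "marker_count"), drop = FALSE])
      sel_fit <- fit_sgb(sel_train, stage_params, seed = seed)
      imp <- permutation_importance(sel_fit, sel_train, K = importance_K,
                                    seed = seed)
      importances[[si]] <- imp
      train_m4 <- select_top_k(train_m3, imp, k = top_k)
      test_m4 <- test_m2[, names(train_m4), drop = FALSE]
      test_m4 <- add_marker_count(marker_matrix(
        test_m4[, setdiff(names(test_m4), "marker_count"), drop = FALSE]))
      if ("M4_topk" %in% models) run_stage("M4_topk", train_m4, test_m4)
      if ("stacked" %in% models) run_stage("stacked", train_m4, test_m4)
    }
  }

  results <- do.call(rbind, results)
  results$model <- factor(results$model, levels = MSA_MODELS)
  out <- structure(list(
    results = results,
    summary = summarise_suite(results),
    importance = aggregate_importance(importances),
    removed_outliers = if (outlier_scope == "all") whole_removed
                       else unique(unlist(removed)),
    predictions = do.call(rbind, predictions),
    plan = plan,
    config = list(models = models, params = params, tune = tune,
                  top_k = top_k, importance_K = importance_K,
                  outlier_sd = outlier_sd, outlier_scope = outlier_scope,
                  nu = nu, threshold = threshold)
  ), class = "msa_suite")
  out
}

summarise_suite <- function(results) {
  agg <- function(v) c(mean = mean(v), sd = stats::sd(v))
  by_model <- split(results, results$model, drop = TRUE)
  rows <- lapply(by_model, function(d) {
    data.frame(model = d$model[1], n_splits = nrow(d),
               accuracy = mean(d$accuracy), accuracy_sd = stats::sd(d$accuracy),
               sensitivity = mean(d$sensitivity),
               sensitivity_sd = stats::sd(d$sensitivity),
               specificity = mean(d$specificity),
               specificity_sd = stats::sd(d$specificity),
               auc = mean(d$auc), auc_sd = stats::sd(d$auc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$model), , drop = FALSE]
}

aggregate_importance <- function(importances) {
  if (length(importances) == 0L) return(NULL)
  all_imp <- do.call(rbind, lapply(importances, as.data.frame))
  agg <- stats::aggregate(importance ~ feature, all_imp, mean)
  agg <- agg[order(-agg$importance), , drop = FALSE]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  class(agg) <- c("importance_table", "data.frame")
  attr(agg, "K") <- attr(importances[[1]], "K")
  agg
}

#' @export
print.msa_suite <- function(x, ...) {
  cat(sprintf("MSA model suite: %d stage(s) over %d split(s)\n",
              length(unique(x$results$model)),
              length(unique(x$results$seed))))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-11s AUC %.3f (SD %.3f)  accuracy %.3f\n",
                s$model[i], s$auc[i], s$auc_sd[i], s$accuracy[i]))
  }
  invisible(x)
}

#' @export
summary.msa_suite <- function(object, ...) {
  structure(list(summary = object$summary,
                 importance = object$importance,
                 n_removed = length(object$removed_outliers),
                 config = object$config),
            class = "summary.msa_suite")
}

#' @export
print.summary.msa_suite <- function(x, ...) {
  cat("Staged MSA model suite\n\nPer-model test metrics",
      "(mean across splits, SD in parentheses):\n")
  s <- x$summary
  cat(sprintf("  %-11s %-18s %-18s %-18s %s\n", "model", "accuracy",
              "sensitivity", "specificity", "AUC"))
  for (i in seq_len(nrow(s))) {
    f <- function(m, sd) sprintf("%.3f (%.3f)", m, sd)
    cat(sprintf("  %-11s %-18s %-18s %-18s %s\n", s$model[i],
                f(s$accuracy[i], s$accuracy_sd[i]),
                f(s$sensitivity[i], s$sensitivity_sd[i]),
                f(s$specificity[i], s$specificity_sd[i]),
                f(s$auc[i], s$auc_sd[i])))
  }
  if (!is.null(x$importance)) {
    cat("\nMarker importance (mean RMSE increase, averaged over splits):\n")
    imp <- utils::head(x$importance, 10)
    for (i in seq_len(nrow(imp))) {
      cat(sprintf("  %2d. %-14s %+.5f\n", imp$rank[i], imp$feature[i],
                  imp$importance[i]))
    }
  }
  if (x$n_removed > 0) {
    cat(sprintf("\nProximity outliers removed (%s scope): %d sample(s)\n",
                x$config$outlier_scope, x$n_removed))
  }
  invisible(x)
}

#' @export
plot.msa_suite <- function(x, metric = "auc", ...) {
  v <- x$results[[metric]]
  boxplot(v ~ droplevels(x$results$model),
          xlab = "model stage", ylab = toupper(metric), ...)
  invisible(x)
}
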
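# One-class SVM scorers and elastic-net model stacking.

#' Fit per-class one-class SVM scorers
#'
#' Trains one radial-kernel one-class support vector machine per class
#' (cancer-only and normal-only). Each scorer examines the core identity
#' of its class alone: its continuous decision value is high for cases
#' typical of the class and low or negative for cases on the extreme edge
#' of the class's feature space. Roughly a fraction `nu` of the training
#' cases of each class fall outside their own scorer's boundary.
#'
#' @param x a [marker_matrix] of training samples with both classes.
#' @param nu one-class SVM nu parameter: upper bound on the training
#'   outlier fraction (default 0.1).
#' @param gamma radial kernel width; `NULL` uses the e1071 default
#'   (1/ncol).
#' @param min_class minimum training samples per class (default 5).
#' @return An object of class `"one_class_pair"`; its predict method
#'   returns a data frame with continuous `cancer_score` and
#'   `normal_score` columns.
#' @export
fit_one_class <- function(x, nu = 0.1, gamma = NULL, min_class = 5) {
  tab <- table(x$status)
  if (length(tab) < 2L || any(tab < min_class)) {
    stop(sprintf("one-class fitting requires >= %d samples per class",
                 min_class), call. = FALSE)
  }
  feats <- feature_columns(x)
  one <- function(cls) {
    xm <- as.matrix(x[x$status == cls, feats, drop = FALSE])
    storage.mode(xm) <- "double"
    args <- list(x = xm, type = "one-classification", kernel = "radial",
                 nu = nu, scale = FALSE)
    if (!is.null(gamma)) args$gamma <- gamma
    do.call(e1071::svm, args)
  }
  structure(list(cancer = one("cancer"), normal = one("normal"),
                 features = feats),
            class = "one_class_pair")
}

#' @describeIn fit_one_class continuous inlier scores for new samples.
#' @param object a fitted `"one_class_pair"`.
#' @param newdata a [marker_matrix] or data frame with the feature
#'   columns.
#' @param ... unused.
#' @export
predict.one_class_pair <- function(object, newdata, ...) {
  xm <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  storage.mode(xm) <- "double"
  score <- function(fit) {
    as.numeric(attr(stats::predict(fit, xm, decision.values = TRUE),
                    "decision.values"))
  }
  data.frame(cancer_score = score(object$cancer),
             normal_score = score(object$normal))
}

#' Combine first-level predictions with elastic-net logistic regression
#'
#' The second layer of the stacked ensemble: an elastic-net-penalised
#' logistic regression over first-level model outputs (the boosting
#' probability and the two one-class scores), with the penalty chosen by
#' internal cross-validation. To avoid leakage the first-level outputs
#' must be computed out-of-fold on the training data (see [fit_stacked],
#' which orchestrates this).
#'
#' @param features data frame or matrix of first-level outputs, one row
#'   per training sample.
#' @param labels training labels (`"cancer"`/`"normal"`), aligned with
#'   `features`.
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param seed RNG seed for the internal CV fold draw.
#' @return An object of class `"stack_fit"`; its predict method maps new
#'   first-level outputs to a final probability of cancer.
#' @export
stack_models <- function(features, labels, alpha = 0.5, seed = 1) {
  features <- as.matrix(as.data.frame(features))
  if (nrow(features) != length(labels)) {
    stop("`features` and `labels` have mismatched lengths", call. = FALSE)
  }
  y <- as.integer(labels == "cancer")
  set.seed(seed)
  constant <- all(apply(features, 2L, stats::var) < .Machine$double.eps)
  if (constant) {
    # intercept-only: predictions collapse to the class prevalence
    fit <- NULL
    prevalence <- mean(y)
  } else {
    fit <- glmnet::cv.glmnet(features, y, family = "binomial",
                             alpha = alpha, nfolds = 5)
    prevalence <- mean(y)
  }
  structure(list(fit = fit, alpha = alpha, prevalence = prevalence,
                 feature_names = colnames(features)),
            class = "stack_fit")
}

#' @describeIn stack_models final stacked probability for new first-level
#'   outputs.
#' @param object a fitted `"stack_fit"`.
#' @param newdata first-level outputs for new samples.
#' @param ... unused.
#' @export
predict.stack_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(as.data.frame(newdata))
  if (is.null(object$fit)) {
    return(rep(object$prevalence, nrow(newdata)))
  }
  as.numeric(stats::predict(object$fit, newdata, s = "lambda.min",
                            type = "response"))
}

#' Fit the full stacked ensemble on a training set
#'
#' Orchestrates the two-layer stack without leakage: first-level features
#' (boosting probability, cancer one-class score, normal one-class score)
#' are generated out-of-fold by 5-fold cross-validation within the
#' training set, the elastic-net combiner is fit on those out-of-fold
#' features, and the first-level models are refit on the full training
#' set for test-time feature generation.
#'
#' @param x a [marker_matrix] of training samples.
#' @param params [sgb_params] for the first-level boosting model.
#' @param nu one-class SVM nu (default 0.1).
#' @param alpha elastic-net mixing (default 0.5).
#' @param seed RNG seed.
#' @return An object of class `"stacked_fit"` whose predict method emits
#'   the final probability of cancer for new samples.
#' @export
fit_stacked <- function(x, params = sgb_params(), nu = 0.1, alpha = 0.5,
                        seed = 1) {
  set.seed(seed)
  folds <- make_folds(x$status, 5)
  oof <- data.frame(sgb_prob = rep(NA_real_, nrow(x)),
                    cancer_score = NA_real_, normal_score = NA_real_)
  for (f in unique(folds)) {
    hold <- which(folds == f)
    train <- x[-hold, , drop = FALSE]
    sgb <- fit_sgb(train, params, seed = seed)
    oc <- fit_one_class(train, nu = nu)
    oof$sgb_prob[hold] <- predict(sgb, x[hold, , drop = FALSE])
    sc <- predict(oc, x[hold, , drop = FALSE])
    oof$cancer_score[hold] <- sc$cancer_score
    oof$normal_score[hold] <- sc$normal_score
  }
  combiner <- stack_models(oof, x$status, alpha = alpha, seed = seed)
  structure(list(
    sgb = fit_sgb(x, params, seed = seed),
    one_class = fit_one_class(x, nu = nu),
    combiner = combiner,
    oof = oof
  ), class = "stacked_fit")
}

#' @describeIn fit_stacked stacked probability of cancer for new samples.
#' @param object a fitted `"stacked_fit"`.
#' @param newdata a [marker_matrix] or data frame with the feature
#'   columns.
#' @param ... unused.
#' @export
predict.stacked_fit <- function(object, newdata, ...) {
  feats <- data.frame(sgb_prob = predict(object$sgb, newdata),
                      predict(object$one_class, newdata))
  predict(object$combiner, feats)
}
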
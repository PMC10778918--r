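# Permutation-based variable importance and marker selection.

#' Permutation variable importance
#'
#' Measures each feature's importance as the mean increase in the model's
#' prediction RMSE caused by randomly permuting that feature's values.
#' With baseline RMSE `s0` and `S_kj` the RMSE after the k-th independent
#' permutation of feature j,
#' `i_j = (1/K) * sum_k S_kj - s0`,
#' so informative features have positive importance and a feature whose
#' permutation cannot change predictions (e.g. a constant column) has
#' importance exactly 0. Features are ranked by descending importance,
#' ties broken by column order. The expectation of `i_j` does not depend
#' on `K`; larger `K` only reduces its Monte-Carlo variance.
#'
#' @param fit a fitted classifier with a `predict(fit, newdata)` method
#'   returning P(cancer), e.g. an [fit_sgb] object.
#' @param data a [marker_matrix] on which to measure importance (normally
#'   the training set).
#' @param K number of permutation repetitions per feature (default 10000).
#' @param features which columns to permute (default: all feature columns
#'   of `data` used by the fit).
#' @param seed RNG seed.
#' @return An object of class `"importance_table"`: data frame with
#'   columns `feature`, `importance`, `rank`, and attribute `K`.
#' @export
permutation_importance <- function(fit, data, K = 10000, features = NULL,
                                   seed = 1) {
  if (!is.numeric(K) || K < 1) stop("`K` must be >= 1", call. = FALSE)
  K <- as.integer(K)
  set.seed(seed)
  feats <- features %||% intersect(feature_columns(data), fit$features)
  y <- as.integer(data$status == "cancer")
  rmse <- function(p) sqrt(mean((p - y)^2))
  s0 <- rmse(predict(fit, data))
  n <- nrow(data)
  imp <- vapply(feats, function(f) {
    perm_scores <- vapply(seq_len(K), function(k) {
      d <- data
      d[[f]] <- d[[f]][sample.int(n)]
      rmse(predict(fit, d))
    }, numeric(1))
    mean(perm_scores) - s0
  }, numeric(1))
  ord <- order(-imp)  # stable: ties keep column order
  out <- data.frame(feature = feats, importance = unname(imp),
                    rank = match(seq_along(feats), ord),
                    stringsAsFactors = FALSE)
  attr(out, "K") <- K
  class(out) <- c("importance_table", "data.frame")
  out
}

#' @export
print.importance_table <- function(x, ...) {
  cat(sprintf("Permutation importance (K = %d repetitions):\n", attr(x, "K")))
  print.data.frame(x[order(x$rank), ], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Keep only the top-k most important markers
#'
#' Reduces a marker matrix to the `k` marker columns ranked most important
#' (engineered features such as `marker_count` are not counted towards `k`;
#' `marker_count`, when present, is recomputed over the kept markers).
#'
#' @param x a [marker_matrix].
#' @param importance an [importance_table] covering the markers of `x`.
#' @param k number of markers to keep (default 8).
#' @return The reduced [marker_matrix].
#' @export
select_top_k <- function(x, importance, k = 8) {
  if (!is.numeric(k) || k < 1) stop("`k` must be a positive count",
                                    call. = FALSE)
  mk <- marker_columns(x)
  imp <- importance[importance$feature %in% mk, , drop = FALSE]
  if (k > nrow(imp)) {
    stop(sprintf("k = %d exceeds the %d ranked markers", k, nrow(imp)),
         call. = FALSE)
  }
  keep <- imp$feature[order(imp$rank)][seq_len(k)]
  had_count <- "marker_count" %in% names(x)
  out <- marker_matrix(x[, c("sample_id", "status", keep), drop = FALSE])
  if (had_count) out <- add_marker_count(out)  # recomputed over kept markers
  out
}
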
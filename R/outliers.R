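# Random-forest proximity-based outlier removal.

#' Random-forest proximity matrix
#'
#' Fits a random-forest classifier of cancer vs normal status and returns
#' the case proximity matrix: entry (i, j) is the fraction of trees in
#' which cases i and j land in the same terminal node. The matrix is
#' symmetric with unit diagonal and entries in \[0, 1\].
#'
#' @param x a [marker_matrix].
#' @param ntree number of trees (default 500).
#' @param seed RNG seed.
#' @return An n x n numeric proximity matrix.
#' @export
rf_proximity <- function(x, ntree = 500, seed = 1) {
  set.seed(seed)
  feats <- feature_columns(x)
  fit <- randomForest::randomForest(
    x = as.data.frame(x[, feats, drop = FALSE]),
    y = factor(x$status),
    ntree = ntree, proximity = TRUE)
  prox <- fit$proximity
  diag(prox) <- 1
  prox
}

#' Remove proximity outliers
#'
#' Scores each case by its mean random-forest proximity to the other
#' cases of its own class; a case lying more than `sd_threshold` standard
#' deviations below its class's mean score sits outside the class boundary
#' defined by the proximity structure and is removed. With fewer than
#' `min_class` samples in either class the proximity estimate is too
#' unstable and the call errors.
#'
#' @param x a [marker_matrix].
#' @param sd_threshold how many SDs below the class mean marks an outlier
#'   (default 1).
#' @param ntree random-forest size (default 500).
#' @param min_class minimum samples required per class (default 10).
#' @param seed RNG seed.
#' @return A list with `matrix` (the reduced [marker_matrix]), `removed`
#'   (sample ids), and `scores` (per-sample mean within-class proximity).
#' @export
remove_outliers_rf <- function(x, sd_threshold = 1, ntree = 500,
                               min_class = 10, seed = 1) {
  tab <- table(x$status)
  if (length(tab) < 2L || any(tab < min_class)) {
    stop(sprintf("outlier removal requires at least %d samples per class",
                 min_class), call. = FALSE)
  }
  prox <- rf_proximity(x, ntree = ntree, seed = seed)
  n <- nrow(x)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(x$status == x$status[i])
    same <- setdiff(same, i)
    scores[i] <- mean(prox[i, same])
  }
  drop <- logical(n)
  for (cls in unique(x$status)) {
    idx <- which(x$status == cls)
    s <- stats::sd(scores[idx])
    if (is.na(s) || s == 0) next  # all equal: nothing is an outlier
    drop[idx] <- scores[idx] < mean(scores[idx]) - sd_threshold * s
  }
  list(matrix = marker_matrix(x[!drop, , drop = FALSE]),
       removed = x$sample_id[drop],
       scores = stats::setNames(scores, x$sample_id))
}
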
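#' Area under the ROC curve with ROC coordinates
#'
#' Computes the area under the receiver operating characteristic curve via
#' the Mann-Whitney rank statistic (ties receive half credit, which makes
#' the value identical to the trapezoidal area under the empirical ROC
#' curve), together with the ROC coordinates themselves.
#'
#' @param scores numeric vector of continuous scores; larger values should
#'   indicate the positive class.
#' @param labels vector coercible to a two-level factor; the positive class
#'   is `positive`.
#' @param positive value of `labels` treated as the positive class
#'   (default `"cancer"`; if absent from `labels`, the last factor level is
#'   used).
#' @return An object of class `"msa_roc"`: a list with elements `auc`
#'   (scalar in \[0, 1\]), and `coords`, a data frame of `threshold`, `fpr`,
#'   `tpr` describing the ROC curve from (0, 0) to (1, 1).
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c("cancer", "cancer", "normal", "normal"))$auc
#' @export
roc_auc <- function(scores, labels, positive = "cancer") {
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have the same length", call. = FALSE)
  }
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L) {
    stop("`labels` must contain exactly two classes", call. = FALSE)
  }
  if (!positive %in% levels(labels)) positive <- levels(labels)[nlevels(labels)]
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # ROC coordinates: step curve over unique thresholds, descending
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / n0, numeric(1))
  coords <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, fpr),
    tpr = c(0, tpr)
  )
  structure(list(auc = auc, coords = coords), class = "msa_roc")
}

#' @export
print.msa_roc <- function(x, ...) {
  cat(sprintf("ROC curve: AUC = %.4f (%d operating points)\n",
              x$auc, nrow(x$coords)))
  invisible(x)
}

#' @export
plot.msa_roc <- function(x, ...) {
  plot(x$coords$fpr, x$coords$tpr, type = "s",
       xlab = "False positive rate", ylab = "True positive rate",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  abline(0, 1, lty = 3, col = "grey60")
  invisible(x)
}

#' Accuracy, sensitivity and specificity at a probability threshold
#'
#' Dichotomises continuous scores at `threshold` and reports the standard
#' confusion-matrix summaries with the cancer class as positive:
#' sensitivity = TP / (TP + FN), specificity = TN / (TN + FP).
#'
#' @param predictions numeric scores or probabilities for the positive class.
#' @param labels two-level class labels aligned with `predictions`.
#' @param threshold score at or above which a case is called positive
#'   (default 0.5).
#' @param positive label value of the positive class (default `"cancer"`).
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @examples
#' confusion_metrics(c(0.9, 0.2, 0.7, 0.4),
#'                   c("cancer", "normal", "normal", "cancer"))
#' @export
confusion_metrics <- function(predictions, labels, threshold = 0.5,
                              positive = "cancer") {
  if (length(predictions) != length(labels)) {
    stop("`predictions` and `labels` must have the same length", call. = FALSE)
  }
  labels <- as.factor(labels)
  if (!positive %in% levels(labels)) positive <- levels(labels)[nlevels(labels)]
  truth <- labels == positive
  called <- predictions >= threshold
  tp <- sum(called & truth)
  tn <- sum(!called & !truth)
  fp <- sum(called & !truth)
  fn <- sum(!called & truth)
  c(accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Two-dimensional PCA view of a marker matrix
#'
#' Centred principal component analysis of the numeric marker columns, with
#' a deterministic sign convention: each component is flipped so that its
#' largest-magnitude loading is positive.
#'
#' @param x a [marker_matrix] or a numeric matrix/data frame of samples in
#'   rows.
#' @return A data frame with columns `PC1`, `PC2` (per-sample scores) plus
#'   `label` when `x` carries labels; attributes `sdev` (all component
#'   standard deviations) and `rotation`.
#' @export
pca_view <- function(x) {
  if (inherits(x, "marker_matrix")) {
    m <- as.matrix(x[, marker_columns(x), drop = FALSE])
    label <- x$status
  } else {
    m <- as.matrix(x)
    label <- NULL
  }
  if (nrow(m) < 3L) stop("need at least 3 samples for a PCA view", call. = FALSE)
  if (all(apply(m, 2L, stats::var) < .Machine$double.eps)) {
    warning("constant matrix: PCA view is all zeros")
    out <- data.frame(PC1 = numeric(nrow(m)), PC2 = numeric(nrow(m)))
    if (!is.null(label)) out$label <- label
    attr(out, "sdev") <- rep(0, min(dim(m)))
    return(out)
  }
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  # sign convention: largest |loading| positive per component
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  k <- min(2L, ncol(p$x))
  out <- as.data.frame(p$x[, seq_len(k), drop = FALSE])
  if (k == 1L) out$PC2 <- 0
  names(out)[1:2] <- c("PC1", "PC2")
  if (!is.null(label)) out$label <- label
  attr(out, "sdev") <- p$sdev
  attr(out, "rotation") <- p$rotation
  out
}
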
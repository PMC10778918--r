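# Repeated train/test partitioning and class rebalancing.

#' Plan of repeated train/test splits
#'
#' Describes the repeated-split evaluation design: a vector of RNG seeds,
#' one per split, each producing an 80/20 train/test partition. The
#' default plan draws 100 distinct seeds from a master seed.
#'
#' @param seeds integer vector of distinct per-split seeds, or `NULL` to
#'   draw `n_splits` seeds from `master_seed`.
#' @param n_splits number of splits when `seeds` is `NULL` (default 100).
#' @param train_fraction fraction of samples assigned to training
#'   (default 0.8); the remainder is the held-out test set, with rounding
#'   in favour of the training set.
#' @param stratified preserve class proportions within each partition
#'   (default `TRUE`).
#' @param master_seed seed used to draw the per-split seeds.
#' @return An object of class `"split_plan"`.
#' @export
split_plan <- function(seeds = NULL, n_splits = 100, train_fraction = 0.8,
                       stratified = TRUE, master_seed = 42) {
  if (is.null(seeds)) {
    set.seed(master_seed)
    seeds <- sample.int(.Machine$integer.max - 1L, n_splits)
  }
  seeds <- as.integer(seeds)
  if (length(seeds) == 0L || anyDuplicated(seeds)) {
    stop("`seeds` must be a non-empty vector of distinct seeds",
         call. = FALSE)
  }
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(seeds = seeds, train_fraction = train_fraction,
                 stratified = isTRUE(stratified)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("Split plan: %d splits, %d%%/%d%% train/test%s\n",
              length(x$seeds), round(100 * x$train_fraction),
              round(100 * (1 - x$train_fraction)),
              if (x$stratified) ", stratified" else ""))
  invisible(x)
}

#' Materialise a split plan on a marker matrix
#'
#' For each seed of the plan, draws disjoint, exhaustive train/test row
#' index sets. The test set receives `floor((1 - train_fraction) * n)`
#' samples (per class when stratified), so rounding favours training.
#' Identical seeds give identical partitions.
#'
#' @param x a [marker_matrix] containing both classes.
#' @param plan a [split_plan].
#' @return A list (one element per seed) of lists with integer vectors
#'   `train` and `test` and the `seed` used.
#' @export
split_data <- function(x, plan = split_plan()) {
  if (length(unique(x$status)) < 2L) {
    stop("cannot split a single-class matrix", call. = FALSE)
  }
  lapply(plan$seeds, function(s) {
    set.seed(s)
    n <- nrow(x)
    if (plan$stratified) {
      test <- integer(0)
      for (cls in unique(x$status)) {
        idx <- which(x$status == cls)
        n_test <- floor((1 - plan$train_fraction) * length(idx) + 1e-9)
        test <- c(test, sample(idx, n_test))
      }
    } else {
      test <- sample(n, floor((1 - plan$train_fraction) * n + 1e-9))
    }
    test <- sort(test)
    list(train = setdiff(seq_len(n), test), test = test, seed = s)
  })
}

#' Up-sample the minority class of a training set
#'
#' Draws samples from the minority class with replacement until both
#' classes are equally frequent. Applied to training data only — the test
#' set is never resampled.
#'
#' @param x a [marker_matrix] of training samples.
#' @param seed optional RNG seed.
#' @return A [marker_matrix] with equal class counts; added rows are
#'   duplicates of original minority rows.
#' @export
upsample_minority <- function(x, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- table(x$status)
  if (length(tab) < 2L) {
    stop("up-sampling requires both classes in the training set",
         call. = FALSE)
  }
  if (tab[1] == tab[2]) return(x)
  minority <- names(tab)[which.min(tab)]
  deficit <- max(tab) - min(tab)
  min_idx <- which(x$status == minority)
  extra <- sample(min_idx, deficit, replace = TRUE)
  out <- rbind(x, x[extra, , drop = FALSE])
  rownames(out) <- NULL
  marker_matrix(out)
}
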
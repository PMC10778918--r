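# Cohort cleaning and binary encoding: sample profiles -> ML-ready matrix.

#' Binary marker matrix
#'
#' The substrate of the modelling pipeline: one row per sample, one 0/1
#' column per marker (1 = LOH-positive), a `status` label column
#' (`"cancer"`/`"normal"`), and optionally an engineered `marker_count`
#' column equal to the row sum of the marker columns.
#'
#' @param df data frame with columns `sample_id`, `status`, binary marker
#'   columns, and optionally `marker_count`.
#' @return The validated data frame with class `"marker_matrix"`.
#' @export
marker_matrix <- function(df) {
  if (!all(c("sample_id", "status") %in% names(df))) {
    stop("a marker matrix needs `sample_id` and `status` columns",
         call. = FALSE)
  }
  if (!all(df$status %in% c("cancer", "normal"))) {
    stop("`status` must be 'cancer' or 'normal'", call. = FALSE)
  }
  mk <- setdiff(names(df), c("sample_id", "status", "marker_count"))
  if (length(mk) == 0L) stop("no marker columns found", call. = FALSE)
  vals <- as.matrix(df[, mk, drop = FALSE])
  if (anyNA(vals) || !all(vals %in% c(0, 1))) {
    stop("marker columns must be 0/1 with no missing values", call. = FALSE)
  }
  if ("marker_count" %in% names(df) &&
      !all(df$marker_count == rowSums(vals))) {
    stop("`marker_count` does not equal the marker row sums", call. = FALSE)
  }
  class(df) <- c("marker_matrix", "data.frame")
  df
}

#' @rdname marker_matrix
#' @param x a `marker_matrix`.
#' @return `marker_columns` returns the marker column names (excluding
#'   `marker_count`).
#' @export
marker_columns <- function(x) {
  setdiff(names(x), c("sample_id", "status", "marker_count"))
}

# all predictor columns (markers + engineered features)
feature_columns <- function(x) {
  setdiff(names(x), c("sample_id", "status"))
}

#' @export
print.marker_matrix <- function(x, ...) {
  mk <- marker_columns(x)
  cat(sprintf("Binary marker matrix: %d samples x %d markers%s\n",
              nrow(x), length(mk),
              if ("marker_count" %in% names(x)) " (+ marker_count)" else ""))
  tab <- table(x$status)
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Remove samples dominated by non-informative loci
#'
#' Implements the cohort cleaning rule: a sample whose loci include
#' `threshold` or more non-informative markers — Non-Informative
#' (homozygous) or Non-Evaluable (insufficient peak height) calls, or a
#' combination of both — carries too little usable signal and is removed.
#' QNS samples (failed acceptance) are excluded first.
#'
#' The filter is idempotent: re-applying it to its own output removes
#' nothing further.
#'
#' @param profiles per-sample profile data frame from [sample_profiles]
#'   (columns `sample_id`, `n_noninformative`, `genotype` used).
#' @param threshold removal threshold (default 5: five or more
#'   non-informative markers).
#' @return A list with `profiles` (retained rows) and `removed` (data
#'   frame of `sample_id` and `reason`).
#' @export
filter_noninformative <- function(profiles, threshold = 5) {
  qns <- !is.na(profiles$genotype) & profiles$genotype == "QNS"
  noninf <- !qns & profiles$n_noninformative >= threshold
  removed <- rbind(
    data.frame(sample_id = profiles$sample_id[qns],
               reason = rep("QNS", sum(qns)),
               stringsAsFactors = FALSE),
    data.frame(sample_id = profiles$sample_id[noninf],
               reason = rep(sprintf(">= %d non-informative markers",
                                    threshold), sum(noninf)),
               stringsAsFactors = FALSE)
  )
  list(profiles = profiles[!qns & !noninf, , drop = FALSE],
       removed = removed)
}

#' Encode locus calls as a binary marker matrix
#'
#' Positive calls become 1; Negative, Non-Informative and Non-Evaluable
#' calls all become 0 ("non-positive"). The output is total: no missing
#' values.
#'
#' @param calls locus calls from [call_cohort].
#' @param labels sample labels: either a named character vector
#'   (`"cancer"`/`"normal"`, names = sample ids) or a data frame with
#'   `sample_id` and `status` columns.
#' @param profiles optional retained profiles (e.g. from
#'   [filter_noninformative]); when given, only those samples are encoded.
#' @return A [marker_matrix] (without `marker_count`; see
#'   [add_marker_count]).
#' @export
binarize <- function(calls, labels, profiles = NULL) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$status, labels$sample_id)
  }
  if (!is.null(profiles)) {
    calls <- calls[calls$sample_id %in% profiles$sample_id, , drop = FALSE]
  }
  samples <- sort(unique(calls$sample_id))
  unlabelled <- setdiff(samples, names(labels))
  if (length(unlabelled) > 0L) {
    stop("sample(s) without a cancer/normal label: ",
         paste(utils::head(unlabelled, 5), collapse = ", "), call. = FALSE)
  }
  markers <- unique(calls$marker)
  wide <- matrix(0L, length(samples), length(markers),
                 dimnames = list(samples, markers))
  pos <- calls[calls$call == "Positive", , drop = FALSE]
  wide[cbind(match(pos$sample_id, samples), match(pos$marker, markers))] <- 1L
  df <- data.frame(sample_id = samples,
                   status = unname(labels[samples]),
                   wide, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(df) <- NULL
  marker_matrix(df)
}

#' Append the marker-burden feature
#'
#' Adds `marker_count`, the total number of positive markers per sample,
#' as an engineered predictor: overall LOH burden is itself predictive of
#' cancer beyond the identity of the positive markers. Marker columns are
#' unchanged.
#'
#' @param x a [marker_matrix].
#' @return The matrix with a `marker_count` column appended (replaced if
#'   already present).
#' @export
add_marker_count <- function(x) {
  stopifnot(inherits(x, "marker_matrix"))
  mk <- marker_columns(x)
  x$marker_count <- as.integer(rowSums(x[, mk, drop = FALSE]))
  marker_matrix(x)
}

#' Read or write a marker matrix CSV
#'
#' CSV with a header row, one sample per row, a `status` column with
#' values `"cancer"`/`"normal"`, and 0/1 marker columns.
#'
#' @param path file path.
#' @return `read_marker_matrix` returns a [marker_matrix];
#'   `write_marker_matrix` returns `path` invisibly.
#' @export
read_marker_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  marker_matrix(df)
}

#' @rdname read_marker_matrix
#' @param x a [marker_matrix].
#' @export
write_marker_matrix <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
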
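# End-to-end orchestration: synthetic generation (or file input) ->
# LOH calling -> cohort prep -> model suite -> report bundle.

#' Run the full MSA analysis pipeline
#'
#' Executes the whole pipeline from exactly one input source:
#' \itemize{
#'   \item a [cohort_spec] — a synthetic cohort is generated, per-marker
#'     cut-offs are calibrated from a matched healthy panel, and LOH is
#'     called from the simulated peaks;
#'   \item a peak table file (with a cut-off file) — LOH is called from
#'     the supplied fragment-analysis export;
#'   \item a marker-matrix CSV — calling is skipped and modelling starts
#'     from the binary matrix.
#' }
#' Calls are turned into sample profiles, QNS and non-informative-heavy
#' samples are removed, the binary matrix is encoded, and the staged
#' model suite is evaluated over repeated splits. All randomness derives
#' from `seed`, so a rerun with the same configuration reproduces the
#' report exactly.
#'
#' @param spec a [cohort_spec] for a synthetic run (its `seed` field is
#'   overridden by `seed`).
#' @param peaks path to a tab-delimited peak table.
#' @param cutoffs path to a YAML/JSON cut-off file (required with
#'   `peaks`); for synthetic runs cut-offs are calibrated from a healthy
#'   panel instead.
#' @param matrix path to a marker-matrix CSV.
#' @param labels optional named vector or data frame of sample labels for
#'   a `peaks` run; synthetic runs carry their own labels.
#' @param out_dir directory for the report bundle (created if needed);
#'   `NULL` skips writing.
#' @param seed single global seed governing every random draw.
#' @param n_splits number of train/test splits for the suite (default 20).
#' @param n_healthy matched healthy pairs for cut-off calibration in
#'   synthetic runs (default 50).
#' @param min_loci minimum qualifying loci for sample acceptance
#'   (default 8).
#' @param noninf_threshold removal threshold for non-informative-heavy
#'   samples (default 5).
#' @param ... further arguments passed to [msa_suite] (e.g. `models`,
#'   `top_k`, `importance_K`, `tune`).
#' @return A list of class `"msa_report"`: the configuration, calibrated
#'   cut-offs, locus calls, sample profiles, removal report, marker
#'   matrix, fitted [msa_suite], and the PCA view.
#' @export
run_msa_analysis <- function(spec = NULL, peaks = NULL, cutoffs = NULL,
                             matrix = NULL, labels = NULL, out_dir = NULL,
                             seed = 1, n_splits = 20, n_healthy = 50,
                             min_loci = 8, noninf_threshold = 5, ...) {
  sources <- c(spec = !is.null(spec), peaks = !is.null(peaks),
               matrix = !is.null(matrix))
  if (sum(sources) != 1L) {
    stop("exactly one input source (spec, peaks or matrix) must be given",
         call. = FALSE)
  }
  if (!is.null(peaks) && is.null(cutoffs)) {
    stop("a peaks run requires a `cutoffs` file", call. = FALSE)
  }
  seed <- as.integer(seed)

  calls <- profiles <- removal <- cutoff_tab <- NULL
  if (!is.null(spec)) {
    spec$seed <- seed
    spec <- validate_cohort_spec(spec)
    healthy_spec <- spec
    healthy_spec$seed <- seed + 1L
    panel <- generate_healthy_panel(n_healthy, healthy_spec)
    cutoff_tab <- calibrate_cutoffs(panel,
                                    min_informative_loci = min_loci)
    cohort <- generate_peak_cohort(spec)
    calls <- call_cohort(cohort$peaks, cutoff_tab)
    sample_labels <- cohort$truth$labels
  } else if (!is.null(peaks)) {
    cutoff_tab <- read_cutoff_table(cutoffs)
    calls <- call_cohort(read_peak_table(peaks), cutoff_tab)
    if (is.null(labels)) {
      stop("a peaks run requires sample `labels`", call. = FALSE)
    }
    sample_labels <- labels
  }

  if (!is.null(calls)) {
    profiles <- sample_profiles(calls, attempts = 2, min_loci = min_loci)
    removal <- filter_noninformative(profiles, threshold = noninf_threshold)
    mm <- binarize(calls, sample_labels, profiles = removal$profiles)
  } else {
    mm <- read_marker_matrix(matrix)
  }

  plan <- split_plan(n_splits = n_splits, master_seed = seed)
  suite <- msa_suite(mm, plan, ...)
  pca <- pca_view(mm)

  report <- structure(list(
    seed = seed,
    input = names(sources)[sources],
    cutoffs = cutoff_tab,
    calls = calls,
    profiles = profiles,
    removal = removal,
    matrix = mm,
    suite = suite,
    pca = pca
  ), class = "msa_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.msa_report <- function(x, ...) {
  cat(sprintf("MSA analysis report (input: %s, seed %d)\n", x$input, x$seed))
  if (!is.null(x$profiles)) {
    cat(sprintf("  %d samples profiled, %d removed in cleaning\n",
                nrow(x$profiles), nrow(x$removal$removed)))
  }
  cat(sprintf("  matrix: %d samples x %d markers\n", nrow(x$matrix),
              length(marker_columns(x$matrix))))
  print(x$suite)
  invisible(x)
}

# write the report bundle: one JSON summary + CSVs for every table
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)
  w <- function(df, f) utils::write.csv(df, path(f), row.names = FALSE)
  if (!is.null(report$calls)) w(report$calls, "calls.csv")
  if (!is.null(report$profiles)) w(report$profiles, "profiles.csv")
  if (!is.null(report$removal)) w(report$removal$removed, "removed_samples.csv")
  write_marker_matrix(report$matrix, path("matrix.csv"))
  w(report$suite$results, "metrics_per_split.csv")
  w(report$suite$summary, "metrics_summary.csv")
  w(report$suite$predictions, "predictions.csv")
  if (!is.null(report$suite$importance)) {
    w(as.data.frame(report$suite$importance), "importance.csv")
  }
  w(report$pca, "pca.csv")
  if (!is.null(report$cutoffs)) {
    write_cutoff_table(report$cutoffs, path("cutoffs.yaml"))
  }
  # pooled ROC coordinates of the last-stage model
  preds <- report$suite$predictions
  last <- utils::tail(intersect(MSA_MODELS, unique(preds$model)), 1)
  pr <- preds[preds$model == last, ]
  roc <- roc_auc(pr$score, pr$status)
  utils::write.csv(roc$coords, path("roc.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    seed = report$seed,
    input = report$input,
    n_samples = nrow(report$matrix),
    n_markers = length(marker_columns(report$matrix)),
    models = report$suite$config$models,
    summary = report$suite$summary,
    pooled_roc_auc = stats::setNames(roc$auc, last),
    n_removed_outliers = length(report$suite$removed_outliers)
  ), path("report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
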
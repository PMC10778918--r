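# Synthetic matched blood/urine cohorts.
#
# The generator emulates the data structure of a capillary-electrophoresis
# fragment-analysis run: one or two allele peaks per sample x marker x
# specimen, log-normal peak heights, allele-balance noise between blood and
# urine, LOH as multiplicative suppression of one urine allele, and
# degradation as urine peaks below the RFU acceptance floor. It makes no
# attempt to model PCR stutter, dye pull-up or mobility artifacts.

#' Generate a matched blood/urine peak-height cohort
#'
#' Simulates per-locus allele peaks for a cohort of cancer and normal
#' samples, together with the planted ground truth. Each sample x marker
#' locus is heterozygous with probability `het_rate` (two blood peaks 4 bp
#' apart) and homozygous otherwise (one peak). Urine mirrors the blood
#' allele sizes; at unaffected heterozygous loci the urine allele balance
#' is perturbed by log-normal noise so the expected urine/blood ratio is 1.
#' True LOH (probability `loh_rates[j]` in cancer urine, `fp_rate` in
#' normal urine, at heterozygous loci) suppresses one randomly chosen urine
#' allele by a factor drawn from `loh_suppression`; a suppressed peak
#' falling below the 200 RFU detection floor is emitted as complete
#' allele dropout. Degraded loci (probability `degrade_rate`) have all
#' urine peaks below 200 RFU.
#'
#' @param spec a [cohort_spec].
#' @return A list with components:
#'   \describe{
#'     \item{peaks}{data frame with columns `sample_id`, `specimen`
#'       (`"blood"`/`"urine"`), `marker`, `allele_size` (bp),
#'       `peak_height` (RFU) — the same dialect [read_peak_table] accepts.}
#'     \item{truth}{list with `labels` (named `"cancer"`/`"normal"` vector),
#'       `informative_markers` (marker names whose LOH rate exceeds the
#'       background `fp_rate`), and `states` (sample x marker character
#'       matrix over `"hom"`, `"het"`, `"het_loh"`, `"degraded"`).}
#'   }
#' @examples
#' cohort <- generate_peak_cohort(cohort_spec(n_cancer = 6, n_normal = 2,
#'                                            seed = 1))
#' head(cohort$peaks)
#' @export
generate_peak_cohort <- function(spec) {
  spec <- validate_cohort_spec(spec)
  if (!is.null(spec$seed)) set.seed(spec$seed)

  n <- spec$n_cancer + spec$n_normal
  ids <- c(sprintf("C%04d", seq_len(spec$n_cancer)),
           sprintf("N%04d", seq_len(spec$n_normal)))
  labels <- stats::setNames(rep(c("cancer", "normal"),
                                c(spec$n_cancer, spec$n_normal)), ids)
  markers <- marker_names(spec$n_markers)

  states <- matrix("", n, spec$n_markers, dimnames = list(ids, markers))
  rows <- vector("list", n * spec$n_markers)
  k <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(spec$n_markers)) {
      het <- stats::runif(1) < spec$het_rate
      loh <- FALSE
      if (het) {
        p_loh <- if (labels[i] == "cancer") spec$loh_rates[j] else spec$fp_rate
        loh <- stats::runif(1) < p_loh
      }
      degraded <- stats::runif(1) < spec$degrade_rate
      states[i, j] <- if (degraded) "degraded"
                      else if (!het) "hom"
                      else if (loh) "het_loh" else "het"
      rows[[k <- k + 1L]] <- simulate_locus(ids[i], markers[j], j, het, loh,
                                            degraded, spec)
    }
  }
  peaks <- do.call(rbind, rows)
  rownames(peaks) <- NULL
  truth <- list(labels = labels,
                informative_markers = markers[spec$loh_rates > spec$fp_rate],
                states = states)
  list(peaks = peaks, truth = truth)
}

# One locus for one sample: blood + urine peak records.
# Allele sizes for marker j sit at 100 + 10j with a 4 bp separation.
# An LOH suppression that would push the affected urine peak below the
# 200 RFU detection floor is emitted as complete allele dropout (the peak
# is absent), which is how such loci present on the instrument.
simulate_locus <- function(id, marker, j, het, loh, degraded, spec) {
  sizes <- 100 + 10 * j + if (het) c(0, 4) else 0
  sdlog <- sqrt(log(1 + spec$peak_cv^2))
  blood <- stats::rlnorm(length(sizes), log(spec$peak_mean), sdlog)
  urine <- blood
  urine_keep <- rep(TRUE, length(sizes))
  if (het) {
    e <- stats::rnorm(1, 0, spec$ratio_noise_sd)
    urine <- blood * exp(c(e / 2, -e / 2))
    if (loh) {
      f <- stats::runif(1, spec$loh_suppression[1], spec$loh_suppression[2])
      a <- sample.int(2L, 1L)
      urine[a] <- urine[a] * f
      if (urine[a] < 200) urine_keep[a] <- FALSE
    }
  }
  if (degraded) {
    urine <- stats::runif(length(urine), 20, 180)
    urine_keep <- rep(TRUE, length(urine))
  }
  rbind(
    data.frame(sample_id = id, specimen = "blood", marker = marker,
               allele_size = sizes,
               peak_height = round(pmax(blood, 1)),
               stringsAsFactors = FALSE),
    data.frame(sample_id = id, specimen = "urine", marker = marker,
               allele_size = sizes[urine_keep],
               peak_height = round(pmax(urine[urine_keep], 1)),
               stringsAsFactors = FALSE)
  )
}

#' Generate a healthy calibration panel of matched pairs
#'
#' Simulates matched blood/urine specimens from healthy donors with no LOH
#' effect, no spurious signal and no degradation — the input
#' [calibrate_cutoffs] expects. Heterozygosity and noise parameters come
#' from `spec`.
#'
#' @param n_pairs number of matched blood/urine pairs (at least 2).
#' @param spec a [cohort_spec]; only the panel, heterozygosity, peak and
#'   noise fields are used.
#' @return A peak table data frame in the [read_peak_table] dialect, with
#'   sample ids `H0001`, `H0002`, ...
#' @export
generate_healthy_panel <- function(n_pairs, spec = cohort_spec()) {
  if (!is.numeric(n_pairs) || length(n_pairs) != 1L || n_pairs < 2) {
    stop("`n_pairs` must be at least 2 to estimate the healthy ratio spread",
         call. = FALSE)
  }
  spec <- validate_cohort_spec(spec)
  healthy <- spec
  healthy$n_cancer <- 0L
  healthy$n_normal <- as.integer(n_pairs)
  healthy$loh_rates <- rep(0, spec$n_markers)
  healthy$fp_rate <- 0
  healthy$degrade_rate <- 0
  cohort <- generate_peak_cohort(healthy)
  cohort$peaks$sample_id <- sub("^N", "H", cohort$peaks$sample_id)
  cohort$peaks
}

#' Generate a binary marker matrix directly
#'
#' Shortcut for ML experiments that bypasses peak simulation: each cancer
#' row draws marker j positive with probability `loh_rates[j]`, each normal
#' row with probability `fp_rate`, independently.
#'
#' @param spec a [cohort_spec]; only the sample counts, `loh_rates` and
#'   `fp_rate` are used.
#' @return A list with `matrix` (a [marker_matrix]) and `truth` (labels and
#'   the planted informative marker set).
#' @examples
#' mm <- generate_marker_matrix(cohort_spec(n_cancer = 30, n_normal = 10,
#'                                          seed = 1))
#' table(mm$matrix$status)
#' @export
generate_marker_matrix <- function(spec) {
  spec <- validate_cohort_spec(spec)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_cancer + spec$n_normal
  ids <- c(sprintf("C%04d", seq_len(spec$n_cancer)),
           sprintf("N%04d", seq_len(spec$n_normal)))
  labels <- rep(c("cancer", "normal"), c(spec$n_cancer, spec$n_normal))
  markers <- marker_names(spec$n_markers)
  p <- outer(labels == "cancer", spec$loh_rates,
             function(is_cancer, r) ifelse(is_cancer, r, spec$fp_rate))
  values <- matrix(as.integer(stats::runif(n * spec$n_markers) < p),
                   n, spec$n_markers, dimnames = list(NULL, markers))
  df <- data.frame(sample_id = ids, status = labels, values,
                   stringsAsFactors = FALSE, check.names = FALSE)
  truth <- list(labels = stats::setNames(labels, ids),
                informative_markers = markers[spec$loh_rates > spec$fp_rate])
  list(matrix = marker_matrix(df), truth = truth)
}

#' Write a peak table to a tab-delimited file
#'
#' Writes the dialect [read_peak_table] reads (GeneMapper-style export:
#' one row per allele peak).
#'
#' @param peaks peak table data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
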
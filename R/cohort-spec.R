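#' Specification of a synthetic matched blood/urine cohort
#'
#' Bundles the parameters of the synthetic cohort generator. The defaults
#' describe the study design the pipeline targets: a 3:1 cancer/normal
#' imbalance (300 vs 100), a 15-marker STR panel with roughly 20% per-locus
#' homozygosity (`het_rate = 0.8`), a subset of markers enriched for LOH in
#' cancer urine, rare spurious LOH signal in normal urine, and occasional
#' degraded loci whose urine peaks fall below the instrument's acceptance
#' floor.
#'
#' @param n_cancer,n_normal number of cancer and normal samples.
#' @param n_markers number of STR markers on the panel.
#' @param het_rate probability that a sample is heterozygous at a marker.
#' @param loh_rates per-marker probability of true LOH in cancer urine at a
#'   heterozygous locus; recycled to length `n_markers`. The default plants
#'   8 informative markers at rate 0.5 and leaves the remainder at the
#'   background rate 0.02.
#' @param fp_rate probability of a spurious LOH-like signal at a
#'   heterozygous locus in normal urine (and at non-enriched loci).
#' @param degrade_rate probability a locus yields insufficient urine peak
#'   height (below the RFU floor).
#' @param peak_mean,peak_cv median and coefficient of variation of the
#'   log-normal peak-height distribution, in RFU.
#' @param ratio_noise_sd standard deviation of the log allele-balance noise
#'   between blood and urine; the urine/blood peak-height ratio at an
#'   unaffected heterozygous locus is `exp(N(0, ratio_noise_sd))`.
#' @param loh_suppression length-2 range; a true LOH event multiplies one
#'   urine allele's height by a factor drawn uniformly from this range.
#' @param seed integer RNG seed; `NULL` leaves the RNG state untouched.
#' @return An object of class `"cohort_spec"` (a validated list).
#' @examples
#' spec <- cohort_spec(n_cancer = 30, n_normal = 10, seed = 1)
#' spec
#' @export
cohort_spec <- function(n_cancer = 300, n_normal = 100, n_markers = 15,
                        het_rate = 0.8,
                        loh_rates = c(rep(0.5, min(8, n_markers)),
                                      rep(0.02, max(0, n_markers - 8))),
                        fp_rate = 0.02, degrade_rate = 0.05,
                        peak_mean = 2000, peak_cv = 0.5,
                        ratio_noise_sd = 0.15,
                        loh_suppression = c(0.1, 0.4),
                        seed = NULL) {
  spec <- list(n_cancer = n_cancer, n_normal = n_normal,
               n_markers = n_markers, het_rate = het_rate,
               loh_rates = rep_len(loh_rates, n_markers),
               fp_rate = fp_rate, degrade_rate = degrade_rate,
               peak_mean = peak_mean, peak_cv = peak_cv,
               ratio_noise_sd = ratio_noise_sd,
               loh_suppression = loh_suppression, seed = seed)
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid cohort_spec: field `%s` %s", field, msg),
         call. = FALSE)
  }
  count1 <- function(field, min = 0L) {
    v <- spec[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < min ||
        v != round(v)) {
      stop_field(field, sprintf("must be a single integer >= %d", min))
    }
  }
  prob <- function(field) {
    v <- spec[[field]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v > 1)) {
      stop_field(field, "must be a probability in [0, 1]")
    }
  }
  count1("n_cancer"); count1("n_normal"); count1("n_markers", min = 1L)
  prob("het_rate"); prob("loh_rates"); prob("fp_rate"); prob("degrade_rate")
  if (length(spec$loh_rates) != spec$n_markers) {
    stop_field("loh_rates", sprintf("must have length n_markers (%d)",
                                    spec$n_markers))
  }
  if (!is.numeric(spec$peak_mean) || spec$peak_mean <= 0) {
    stop_field("peak_mean", "must be positive")
  }
  if (spec$peak_mean < 200 || spec$peak_mean > 100000) {
    stop_field("peak_mean",
               "must lie inside the RFU acceptance window [200, 100000]")
  }
  if (!is.numeric(spec$peak_cv) || spec$peak_cv < 0) {
    stop_field("peak_cv", "must be non-negative")
  }
  if (!is.numeric(spec$ratio_noise_sd) || spec$ratio_noise_sd < 0) {
    stop_field("ratio_noise_sd", "must be non-negative")
  }
  s <- spec$loh_suppression
  if (!is.numeric(s) || length(s) != 2L || any(s <= 0) || any(s >= 1) ||
      s[1] > s[2]) {
    stop_field("loh_suppression", "must be an increasing range within (0, 1)")
  }
  if (!is.null(spec$seed)) {
    if (!is.numeric(spec$seed) || length(spec$seed) != 1L || is.na(spec$seed)) {
      stop_field("seed", "must be a single number or NULL")
    }
  }
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic MSA cohort specification\n")
  cat(sprintf("  samples: %d cancer / %d normal (%.1f:1)\n",
              x$n_cancer, x$n_normal,
              if (x$n_normal > 0) x$n_cancer / x$n_normal else NA_real_))
  cat(sprintf("  markers: %d; het rate %.2f; degrade rate %.2f\n",
              x$n_markers, x$het_rate, x$degrade_rate))
  cat(sprintf("  LOH rates: %s (fp rate %.3f)\n",
              paste(format(x$loh_rates, digits = 2), collapse = " "),
              x$fp_rate))
  cat(sprintf("  peaks: median %g RFU, CV %.2f; log-ratio noise SD %.2f\n",
              x$peak_mean, x$peak_cv, x$ratio_noise_sd))
  invisible(x)
}

# panel marker names: zero-padded, stable ordering
marker_names <- function(n) sprintf("M%02d", seq_len(n))
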
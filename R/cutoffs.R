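#' Per-marker LOH ratio cut-off table
#'
#' Holds the lower and upper urine/blood ratio bounds used to score a
#' heterozygous locus as LOH-positive, plus the global instrument
#' acceptance settings: the RFU peak-height window and the minimum number
#' of qualifying loci a sample must yield.
#'
#' @param markers character vector of marker names.
#' @param lower,upper numeric vectors of per-marker ratio bounds, recycled
#'   to `length(markers)`; each must satisfy `0 < lower < 1 < upper`.
#' @param rfu_min,rfu_max peak-height acceptance window in RFU
#'   (defaults 200 and 100000).
#' @param min_informative_loci minimum count of qualifying (Negative,
#'   Positive or Non-Informative) loci for sample acceptance (default 8).
#' @return An object of class `"cutoff_table"`: a data frame with columns
#'   `marker`, `lower`, `upper` and attributes `rfu_min`, `rfu_max`,
#'   `min_informative_loci`.
#' @examples
#' cutoff_table(c("M01", "M02"), lower = 0.5, upper = 2)
#' @export
cutoff_table <- function(markers, lower = 0.5, upper = 2,
                         rfu_min = 200, rfu_max = 100000,
                         min_informative_loci = 8) {
  lower <- rep_len(lower, length(markers))
  upper <- rep_len(upper, length(markers))
  if (any(lower <= 0) || any(lower >= 1) || any(upper <= 1)) {
    stop("cut-offs must satisfy 0 < lower < 1 < upper for every marker",
         call. = FALSE)
  }
  if (!(rfu_min < rfu_max)) stop("rfu_min must be below rfu_max", call. = FALSE)
  out <- data.frame(marker = as.character(markers), lower = lower,
                    upper = upper, stringsAsFactors = FALSE)
  attr(out, "rfu_min") <- rfu_min
  attr(out, "rfu_max") <- rfu_max
  attr(out, "min_informative_loci") <- min_informative_loci
  class(out) <- c("cutoff_table", "data.frame")
  out
}

#' @export
print.cutoff_table <- function(x, ...) {
  cat(sprintf(
    "LOH cut-off table: %d markers; RFU window [%g, %g]; min %d loci\n",
    nrow(x), attr(x, "rfu_min"), attr(x, "rfu_max"),
    attr(x, "min_informative_loci")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

cutoff_row <- function(cutoffs, marker) {
  i <- match(marker, cutoffs$marker)
  if (is.na(i)) {
    stop(sprintf("marker '%s' has no entry in the cut-off table", marker),
         call. = FALSE)
  }
  cutoffs[i, ]
}

#' Read or write a cut-off table as YAML or JSON
#'
#' The on-disk form is a mapping with keys `rfu_min`, `rfu_max`,
#' `min_informative_loci` and `markers`, the latter keyed by marker name
#' with `lower`/`upper` entries. The format is chosen by file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param path file path.
#' @return `read_cutoff_table` returns a [cutoff_table];
#'   `write_cutoff_table` returns `path` invisibly.
#' @export
read_cutoff_table <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(x$markers) || length(x$markers) == 0L) {
    stop("cut-off file has no `markers` entry: ", path, call. = FALSE)
  }
  m <- x$markers
  cutoff_table(
    markers = names(m),
    lower = vapply(m, function(e) as.numeric(e$lower), numeric(1)),
    upper = vapply(m, function(e) as.numeric(e$upper), numeric(1)),
    rfu_min = x$rfu_min %||% 200,
    rfu_max = x$rfu_max %||% 100000,
    min_informative_loci = x$min_informative_loci %||% 8
  )
}

#' @rdname read_cutoff_table
#' @param cutoffs a [cutoff_table].
#' @export
write_cutoff_table <- function(cutoffs, path) {
  obj <- list(
    rfu_min = attr(cutoffs, "rfu_min"),
    rfu_max = attr(cutoffs, "rfu_max"),
    min_informative_loci = attr(cutoffs, "min_informative_loci"),
    markers = stats::setNames(
      lapply(seq_len(nrow(cutoffs)), function(i) {
        list(lower = cutoffs$lower[i], upper = cutoffs$upper[i])
      }),
      cutoffs$marker)
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' Calibrate per-marker cut-offs from a healthy panel
#'
#' Estimates the LOH decision bounds for each marker from the urine/blood
#' peak-height ratios of matched healthy specimens, the way assay
#' qualification panels are used: at every heterozygous locus of every
#' healthy pair the ratio is computed, and the cut-offs are placed at
#' `exp(mean +/- k * sd)` of the log ratios. Healthy ratios scatter
#' log-symmetrically around 1, so the bounds bracket 1; with `k = 3` about
#' 0.3% of healthy heterozygous loci fall outside them under log-normal
#' noise.
#'
#' A marker with fewer than 2 heterozygous pairs cannot yield a spread
#' estimate: it is flagged (attribute `"flagged"`) and omitted from the
#' table. A degenerate panel with zero ratio variance would collapse the
#' bounds onto 1; a minimum half-width of `min_log_width` on the log scale
#' is enforced around 1 (and around any too-narrow interval).
#'
#' @param panel peak table of matched healthy blood/urine pairs (the
#'   [read_peak_table] dialect), e.g. from [generate_healthy_panel].
#' @param k number of log-scale standard deviations (default 3).
#' @param min_log_width minimum half-width of the log-ratio interval
#'   (default 0.05).
#' @param rfu_min,rfu_max,min_informative_loci passed to [cutoff_table].
#' @return A [cutoff_table] for the calibratable markers; markers skipped
#'   for lack of heterozygous pairs are listed in `attr(x, "flagged")`.
#' @export
calibrate_cutoffs <- function(panel, k = 3, min_log_width = 0.05,
                              rfu_min = 200, rfu_max = 100000,
                              min_informative_loci = 8) {
  loci <- consolidate_peaks(panel)
  markers <- sort(unique(panel$marker))
  lower <- upper <- numeric(0)
  kept <- character(0)
  flagged <- character(0)
  for (m in markers) {
    ratios <- healthy_marker_ratios(loci, m)
    if (length(ratios) < 2L) {
      flagged <- c(flagged, m)
      next
    }
    lr <- log(ratios)
    half <- max(k * stats::sd(lr), min_log_width)
    lo <- exp(mean(lr) - half)
    hi <- exp(mean(lr) + half)
    # guarantee the interval brackets 1 (a valid table requires lo < 1 < hi)
    lo <- min(lo, exp(-min_log_width))
    hi <- max(hi, exp(min_log_width))
    kept <- c(kept, m)
    lower <- c(lower, lo)
    upper <- c(upper, hi)
  }
  if (length(kept) == 0L) {
    stop("no marker had >= 2 heterozygous healthy pairs; cannot calibrate",
         call. = FALSE)
  }
  out <- cutoff_table(kept, lower, upper, rfu_min = rfu_min,
                      rfu_max = rfu_max,
                      min_informative_loci = min_informative_loci)
  attr(out, "flagged") <- flagged
  out
}

# ratios of all heterozygous matched pairs for one marker
healthy_marker_ratios <- function(loci, marker) {
  sel <- loci[vapply(loci, function(l) l$marker == marker, logical(1))]
  by_sample <- split(sel, vapply(sel, function(l) l$sample_id, character(1)))
  ratios <- vapply(by_sample, function(pair) {
    sp <- vapply(pair, function(l) l$specimen, character(1))
    u <- pair[[match("urine", sp)]]
    b <- pair[[match("blood", sp)]]
    if (is.null(u) || is.null(b) || anyNA(match(c("urine", "blood"), sp))) {
      return(NA_real_)
    }
    if (nrow(u$alleles) != 2L || nrow(b$alleles) != 2L) return(NA_real_)
    tryCatch(loh_ratio(u, b), error = function(e) NA_real_)
  }, numeric(1))
  ratios[!is.na(ratios)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
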
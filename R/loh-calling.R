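# LOH calling from matched blood/urine fragment-analysis peak tables.
#
# A locus is scored from the urine/blood allele peak-height ratio
#   Ratio = (urine allele1 / urine allele2) / (blood allele1 / blood allele2)
# with allele 1 the smaller-size allele in both specimens. Heterozygous
# loci whose ratio escapes the per-marker cut-offs are Positive (LOH);
# homozygous blood loci are Non-Informative; loci with peaks outside the
# RFU acceptance window are Non-Evaluable.

CALL_LEVELS <- c("Negative", "Positive", "NonInformative", "NonEvaluable")

#' Read a tab-delimited fragment-analysis peak table
#'
#' Reads the GeneMapper-style export dialect: one row per allele peak with
#' columns `sample_id`, `specimen` (`"blood"` or `"urine"`), `marker`,
#' `allele_size` (bp) and `peak_height` (RFU). Malformed rows are reported
#' with their line numbers (header = line 1).
#'
#' @param path path to a tab-delimited text file.
#' @return A data frame of validated peak records.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("peak table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("sample_id", "specimen", "marker", "allele_size",
                "peak_height")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("peak table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lines <- seq_len(nrow(df)) + 1L
  size <- suppressWarnings(as.numeric(df$allele_size))
  height <- suppressWarnings(as.numeric(df$peak_height))
  bad <- which(is.na(size) | is.na(height) | height <= 0)
  if (length(bad) > 0L) {
    stop(sprintf(
      "non-numeric or non-positive allele_size/peak_height at line(s) %s",
      paste(lines[bad], collapse = ", ")), call. = FALSE)
  }
  bad_spec <- which(!df$specimen %in% c("blood", "urine"))
  if (length(bad_spec) > 0L) {
    stop(sprintf(
      "unknown specimen value '%s' at line %d (expected 'blood' or 'urine')",
      df$specimen[bad_spec[1]], lines[bad_spec[1]]), call. = FALSE)
  }
  data.frame(sample_id = df$sample_id, specimen = df$specimen,
             marker = df$marker, allele_size = size, peak_height = height,
             stringsAsFactors = FALSE)
}

#' Consolidate raw peak records into a locus
#'
#' Reduces the peak records of one sample x marker x specimen to at most
#' two alleles: if more than two peaks are present (e.g. stutter or
#' pull-up surviving upstream filtering), the two tallest are kept; alleles
#' are then ordered by ascending size, so allele 1 is the smaller allele.
#'
#' @param records data frame of peak rows for a single sample x marker x
#'   specimen.
#' @return A locus object: list with `sample_id`, `marker`, `specimen` and
#'   `alleles`, a data frame of `size` and `height` with 1 or 2 rows.
#' @export
consolidate_locus <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("consolidate_locus() requires at least one peak record",
         call. = FALSE)
  }
  key <- unique(records[, c("sample_id", "marker", "specimen")])
  if (nrow(key) != 1L) {
    stop("records span more than one sample x marker x specimen",
         call. = FALSE)
  }
  if (nrow(records) > 2L) {
    records <- records[order(-records$peak_height), ][1:2, ]
  }
  records <- records[order(records$allele_size), ]
  list(sample_id = key$sample_id, marker = key$marker,
       specimen = key$specimen,
       alleles = data.frame(size = records$allele_size,
                            height = records$peak_height))
}

# consolidate a whole peak table; returns a list of locus objects
consolidate_peaks <- function(peaks) {
  keys <- paste(peaks$sample_id, peaks$marker, peaks$specimen, sep = "\r")
  lapply(split(peaks, keys), consolidate_locus)
}

#' Urine/blood allele peak-height ratio at a heterozygous locus
#'
#' Computes
#' `(urine allele1 height / urine allele2 height) /
#'  (blood allele1 height / blood allele2 height)`
#' with allele 1 the smaller-size allele in both specimens. Urine alleles
#' are matched to blood alleles by nearest size within `tol` bp; both
#' specimens must be heterozygous (use [call_locus] for the full decision
#' rule including homozygous and dropout handling).
#'
#' @param urine,blood locus objects from [consolidate_locus], each with two
#'   alleles.
#' @param tol allele size matching tolerance in bp (default 1).
#' @return The ratio, a positive scalar; 1 means perfectly preserved allele
#'   balance.
#' @examples
#' u <- consolidate_locus(data.frame(sample_id = "s", marker = "m",
#'   specimen = "urine", allele_size = c(150, 154),
#'   peak_height = c(500, 2000)))
#' b <- consolidate_locus(data.frame(sample_id = "s", marker = "m",
#'   specimen = "blood", allele_size = c(150, 154),
#'   peak_height = c(1000, 1000)))
#' loh_ratio(u, b)  # 0.25
#' @export
loh_ratio <- function(urine, blood, tol = 1) {
  if (nrow(urine$alleles) != 2L || nrow(blood$alleles) != 2L) {
    stop("loh_ratio() requires two alleles in both specimens ",
         "(homozygous loci are non-informative)", call. = FALSE)
  }
  if (any(urine$alleles$height <= 0) || any(blood$alleles$height <= 0)) {
    stop("all four peak heights must be positive", call. = FALSE)
  }
  d <- abs(urine$alleles$size - blood$alleles$size)
  if (any(d > tol)) {
    stop(sprintf(
      "allele sizes differ between specimens by more than %g bp", tol),
      call. = FALSE)
  }
  (urine$alleles$height[1] / urine$alleles$height[2]) /
    (blood$alleles$height[1] / blood$alleles$height[2])
}

#' Call one locus: Negative, Positive, Non-Informative or Non-Evaluable
#'
#' Applies the locus decision rule. In order: any required peak absent or
#' outside the RFU acceptance window makes the locus Non-Evaluable; a
#' homozygous blood locus is Non-Informative (LOH is only detectable at
#' heterozygous loci); otherwise the urine/blood ratio is compared to the
#' marker's cut-offs — strictly below the lower or strictly above the upper
#' cut-off is Positive (LOH), a ratio at or within the bounds is Negative.
#'
#' A heterozygous blood locus whose urine shows only one in-window allele
#' (complete dropout of the other) is scored Positive with the missing
#' allele's height imputed at the detection floor `rfu_min`, and flagged
#' `dropout`: complete allele loss is the strongest LOH signal, and the
#' imputation keeps the ratio finite.
#'
#' @param urine,blood locus objects from [consolidate_locus], or `NULL`
#'   when the specimen produced no peaks.
#' @param cutoffs a [cutoff_table].
#' @param marker marker name; must be present in `cutoffs`.
#' @return A list with `call` (one of `"Negative"`, `"Positive"`,
#'   `"NonInformative"`, `"NonEvaluable"`), `ratio` (numeric, `NA` unless
#'   the call is Negative or Positive) and `flag` (`""` or `"dropout"`).
#' @export
call_locus <- function(urine, blood, cutoffs, marker) {
  cc <- cutoff_row(cutoffs, marker)
  rfu_min <- attr(cutoffs, "rfu_min")
  rfu_max <- attr(cutoffs, "rfu_max")
  in_window <- function(h) h >= rfu_min & h <= rfu_max
  result <- function(call, ratio = NA_real_, flag = "") {
    list(call = call, ratio = ratio, flag = flag)
  }

  # evaluability gate first: all required peaks (both specimens) present
  # and inside the RFU window; only then can homozygosity be interpreted
  if (is.null(blood) || !all(in_window(blood$alleles$height)) ||
      is.null(urine) || !all(in_window(urine$alleles$height))) {
    return(result("NonEvaluable"))
  }
  if (nrow(blood$alleles) == 1L) {
    return(result("NonInformative"))
  }

  if (nrow(urine$alleles) == 1L) {
    # complete dropout of one urine allele: impute at the detection floor
    i <- which.min(abs(blood$alleles$size - urine$alleles$size))
    if (abs(blood$alleles$size[i] - urine$alleles$size) > 1) {
      return(result("NonEvaluable"))
    }
    heights <- c(NA_real_, NA_real_)
    heights[i] <- urine$alleles$height
    heights[-i] <- rfu_min
    u2 <- urine
    u2$alleles <- data.frame(size = blood$alleles$size, height = heights)
    ratio <- loh_ratio(u2, blood)
    return(result("Positive", ratio, "dropout"))
  }

  ratio <- loh_ratio(urine, blood)
  call <- if (ratio < cc$lower || ratio > cc$upper) "Positive" else "Negative"
  result(call, ratio)
}

#' Call every locus of a cohort peak table
#'
#' Consolidates a peak table and emits exactly one call per sample x
#' marker for every marker in the cut-off table, including Non-Evaluable
#' calls for loci with no peaks at all. Calls do not depend on the row
#' order of the input.
#'
#' @param peaks peak table data frame ([read_peak_table] dialect).
#' @param cutoffs a [cutoff_table]; its markers define the panel.
#' @return Data frame with columns `sample_id`, `marker`, `call` (factor
#'   over the four levels), `ratio`, `flag`.
#' @examples
#' cohort <- generate_peak_cohort(cohort_spec(n_cancer = 4, n_normal = 2,
#'                                            seed = 1))
#' cutoffs <- cutoff_table(sprintf("M%02d", 1:15))
#' head(call_cohort(cohort$peaks, cutoffs))
#' @export
call_cohort <- function(peaks, cutoffs) {
  loci <- consolidate_peaks(peaks)
  lkey <- vapply(loci, function(l) {
    paste(l$sample_id, l$marker, l$specimen, sep = "\r")
  }, character(1))
  names(loci) <- lkey
  samples <- sort(unique(peaks$sample_id))
  markers <- cutoffs$marker
  grid <- expand.grid(sample_id = samples, marker = markers,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    s <- grid$sample_id[i]
    m <- grid$marker[i]
    call_locus(loci[[paste(s, m, "urine", sep = "\r")]],
               loci[[paste(s, m, "blood", sep = "\r")]],
               cutoffs, m)
  })
  data.frame(
    sample_id = grid$sample_id,
    marker = grid$marker,
    call = factor(vapply(res, `[[`, character(1), "call"),
                  levels = CALL_LEVELS),
    ratio = vapply(res, `[[`, numeric(1), "ratio"),
    flag = vapply(res, `[[`, character(1), "flag"),
    stringsAsFactors = FALSE
  )
}

#' Sample acceptance decision
#'
#' A sample is accepted when at least `min_loci` of its loci qualify, i.e.
#' received a Negative, Positive or Non-Informative call (Non-Evaluable
#' loci do not count). A sample failing on its first attempt is flagged for
#' one repeat analysis; a sample failing after two attempts is reported as
#' QNS (quantity not sufficient).
#'
#' @param calls data frame of locus calls for one sample (a subset of
#'   [call_cohort] output).
#' @param attempts how many times this sample has been analysed (1 or 2).
#' @param min_loci minimum qualifying loci (default 8).
#' @return A list with `sample_id`, `accepted`, `attempts`, `needs_repeat`,
#'   `n_positive`, `n_noninformative` (Non-Informative + Non-Evaluable
#'   count) and `genotype` (one of `"negative"`, `"LOH-low"`,
#'   `"LOH-medium"`, `"LOH-high"`, `"QNS"`, or `NA` while a repeat is
#'   pending).
#' @export
accept_sample <- function(calls, attempts = 1, min_loci = 8) {
  if (!attempts %in% c(1, 2)) {
    stop("`attempts` must be 1 or 2 (analysis is repeated at most once)",
         call. = FALSE)
  }
  qualifying <- sum(calls$call %in% c("Negative", "Positive",
                                      "NonInformative"))
  accepted <- qualifying >= min_loci
  n_pos <- sum(calls$call == "Positive")
  n_noninf <- sum(calls$call %in% c("NonInformative", "NonEvaluable"))
  genotype <- if (accepted) {
    overall_genotype(calls)
  } else if (attempts >= 2) {
    "QNS"
  } else {
    NA_character_
  }
  list(sample_id = unique(calls$sample_id),
       accepted = accepted,
       attempts = attempts,
       needs_repeat = !accepted && attempts < 2,
       n_positive = n_pos,
       n_noninformative = n_noninf,
       genotype = genotype)
}

#' Overall MSA genotype from positive-marker count
#'
#' Bins the number of LOH-positive markers of an accepted sample:
#' 0 is `"negative"`, 1–2 `"LOH-low"`, 3–4 `"LOH-medium"`, 5 or more
#' `"LOH-high"`.
#'
#' @param calls data frame of locus calls for one accepted sample.
#' @return A single character genotype category.
#' @export
overall_genotype <- function(calls) {
  n <- sum(calls$call == "Positive")
  if (n == 0) "negative"
  else if (n <= 2) "LOH-low"
  else if (n <= 4) "LOH-medium"
  else "LOH-high"
}

#' Per-sample acceptance profiles for a whole cohort
#'
#' Applies [accept_sample] to every sample in a calls table.
#'
#' @param calls output of [call_cohort].
#' @param attempts analysis attempt count applied to every sample
#'   (default 2: treat the table as the final attempt, so failures are
#'   QNS).
#' @param min_loci minimum qualifying loci (default 8).
#' @return Data frame with one row per sample: `sample_id`, `accepted`,
#'   `attempts`, `n_positive`, `n_noninformative`, `genotype`.
#' @export
sample_profiles <- function(calls, attempts = 2, min_loci = 8) {
  by_sample <- split(calls, calls$sample_id)
  rows <- lapply(by_sample, function(cs) {
    p <- accept_sample(cs, attempts = attempts, min_loci = min_loci)
    data.frame(sample_id = p$sample_id, accepted = p$accepted,
               attempts = p$attempts, n_positive = p$n_positive,
               n_noninformative = p$n_noninformative,
               genotype = ifelse(is.na(p$genotype), NA_character_,
                                 p$genotype),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gate a run on its positive control
#'
#' An analysis run is only acceptable when the positive control sample
#' meets strict peak criteria: every expected control locus must show a
#' peak within 1 bp of its expected allele size, with height inside the
#' RFU acceptance window.
#'
#' @param control_peaks peak table rows for the control sample (possibly
#'   empty or `NULL` when the control is missing from the run).
#' @param expected data frame with columns `marker` and `allele_size`
#'   giving the expected control peaks.
#' @param cutoffs a [cutoff_table] supplying the RFU window.
#' @param size_tol allele-size tolerance in bp (default 1).
#' @return A list with `pass` (logical) and `reason` (`""` on pass;
#'   `"no control"` when `control_peaks` is absent/empty; otherwise a
#'   description of the first failing locus).
#' @export
validate_positive_control <- function(control_peaks, expected, cutoffs,
                                      size_tol = 1) {
  if (is.null(control_peaks) || nrow(control_peaks) == 0L) {
    return(list(pass = FALSE, reason = "no control"))
  }
  rfu_min <- attr(cutoffs, "rfu_min")
  rfu_max <- attr(cutoffs, "rfu_max")
  for (i in seq_len(nrow(expected))) {
    m <- expected$marker[i]
    sz <- expected$allele_size[i]
    cand <- control_peaks[control_peaks$marker == m &
                            abs(control_peaks$allele_size - sz) <= size_tol, ]
    if (nrow(cand) == 0L) {
      return(list(pass = FALSE,
                  reason = sprintf("missing control peak: %s @ %g bp", m, sz)))
    }
    if (!any(cand$peak_height >= rfu_min & cand$peak_height <= rfu_max)) {
      return(list(pass = FALSE,
                  reason = sprintf("control peak out of RFU window: %s @ %g bp",
                                   m, sz)))
    }
  }
  list(pass = TRUE, reason = "")
}
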
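# LOH calling: parsing, consolidation, the ratio formula, the four-level
# decision rule, sample acceptance and cut-off calibration.

test_that("peak table parsing validates columns, values and specimens", {
  path <- withr::local_tempfile(fileext = ".tsv")
  peaks <- rbind(peak_rows("S1", "blood", "M01", c(150, 154), c(900, 700)),
                 peak_rows("S1", "urine", "M01", c(150, 154), c(880, 720)))
  write_peak_table(peaks, path)
  parsed <- read_peak_table(path)
  expect_equal(nrow(parsed), 4)
  expect_type(parsed$peak_height, "double")

  bad <- peaks
  names(bad)[2] <- "tissue"
  utils::write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_peak_table(path), "specimen")

  bad2 <- peaks
  bad2$specimen[3] <- "saliva"
  utils::write.table(bad2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_peak_table(path), "saliva.*line 4")

  bad3 <- peaks
  bad3$peak_height[2] <- "tall"
  utils::write.table(bad3, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_peak_table(path), "line\\(s\\) 3")
})

test_that("consolidation keeps the two tallest peaks ordered by size", {
  rec <- peak_rows("S1", "urine", "M01", c(154, 150), c(700, 900))
  l <- consolidate_locus(rec)
  expect_equal(l$alleles$size, c(150, 154))
  expect_equal(l$alleles$height, c(900, 700))

  rec3 <- peak_rows("S1", "urine", "M01", c(150, 154, 158),
                    c(900, 700, 50))
  l3 <- consolidate_locus(rec3)
  expect_equal(nrow(l3$alleles), 2)
  expect_equal(l3$alleles$size, c(150, 154))

  single <- consolidate_locus(peak_rows("S1", "blood", "M01", 150, 900))
  expect_equal(nrow(single$alleles), 1)
  expect_error(consolidate_locus(rec[0, ]), "at least one")
})

test_that("the ratio formula matches hand arithmetic and its symmetries", {
  b11 <- locus("blood", c(150, 154), c(1000, 1000))
  expect_equal(loh_ratio(locus("urine", c(150, 154), c(1000, 1000)), b11), 1)
  expect_equal(loh_ratio(locus("urine", c(150, 154), c(500, 2000)), b11),
               0.25)
  expect_equal(loh_ratio(locus("urine", c(150, 154), c(1000, 1000)),
                         locus("blood", c(150, 154), c(500, 2000))), 4)

  # swapping allele labels consistently in both specimens inverts the ratio
  u <- locus("urine", c(150, 154), c(500, 2000))
  r <- loh_ratio(u, b11)
  u_sw <- locus("urine", c(150, 154), c(2000, 500))
  expect_equal(loh_ratio(u_sw, b11), 1 / r)

  expect_error(loh_ratio(locus("urine", 150, 900), b11), "two alleles")
  expect_error(
    loh_ratio(locus("urine", c(150, 158), c(900, 700)), b11),
    "more than 1 bp")
})

test_that("locus calls follow the four-level decision rule", {
  ct <- cutoff_table("M01", lower = 0.5, upper = 2)
  b_het <- locus("blood", c(150, 154), c(1000, 1000))

  # homozygous blood is non-informative regardless of urine
  expect_equal(call_locus(locus("urine", c(150, 154), c(900, 700)),
                          locus("blood", 150, 900), ct, "M01")$call,
               "NonInformative")
  # LOH: ratio 0.25 escapes (0.5, 2)
  res <- call_locus(locus("urine", c(150, 154), c(500, 2000)), b_het,
                    ct, "M01")
  expect_equal(res$call, "Positive")
  expect_equal(res$ratio, 0.25)
  # peak below the RFU floor
  expect_equal(call_locus(locus("urine", c(150, 154), c(150, 900)), b_het,
                          ct, "M01")$call, "NonEvaluable")
  # peak above the RFU ceiling
  expect_equal(call_locus(locus("urine", c(150, 154), c(900, 150000)),
                          b_het, ct, "M01")$call, "NonEvaluable")
  # absent specimens
  expect_equal(call_locus(NULL, b_het, ct, "M01")$call, "NonEvaluable")
  expect_equal(call_locus(locus("urine", c(150, 154), c(900, 700)), NULL,
                          ct, "M01")$call, "NonEvaluable")
  # boundary ratio is Negative (cut-off inclusive to Negative)
  expect_equal(call_locus(locus("urine", c(150, 154), c(500, 1000)), b_het,
                          ct, "M01")$call, "Negative")
  # complete urine allele dropout: Positive, flagged, ratio from the floor
  drop <- call_locus(locus("urine", 150, 900), b_het, ct, "M01")
  expect_equal(drop$call, "Positive")
  expect_equal(drop$flag, "dropout")
  expect_equal(drop$ratio, (900 / 200) / 1)
  expect_error(call_locus(NULL, b_het, ct, "M99"), "M99")
})

test_that("calls are invariant to peak-table row order and exhaustive", {
  spec <- cohort_spec(n_cancer = 6, n_normal = 3, seed = 31)
  cohort <- generate_peak_cohort(spec)
  ct <- cutoff_table(sprintf("M%02d", 1:15))
  calls1 <- call_cohort(cohort$peaks, ct)
  shuffled <- cohort$peaks[sample(nrow(cohort$peaks)), ]
  calls2 <- call_cohort(shuffled, ct)
  o <- function(d) d[order(d$sample_id, d$marker), ]
  expect_equal(o(calls1), o(calls2), ignore_attr = TRUE)
  # exactly one call per sample x marker
  expect_equal(nrow(calls1), 9 * 15)
  expect_false(anyNA(calls1$call))
})

test_that("sample acceptance applies the 8-locus and repeat rules", {
  ok <- accept_sample(make_calls(n_neg = 6, n_ni = 2, n_ne = 7))
  expect_true(ok$accepted)
  expect_equal(ok$genotype, "negative")

  first_fail <- accept_sample(make_calls(n_neg = 7, n_ne = 8), attempts = 1)
  expect_false(first_fail$accepted)
  expect_true(first_fail$needs_repeat)
  expect_true(is.na(first_fail$genotype))

  second_fail <- accept_sample(make_calls(n_neg = 7, n_ne = 8), attempts = 2)
  expect_false(second_fail$accepted)
  expect_false(second_fail$needs_repeat)
  expect_equal(second_fail$genotype, "QNS")
  expect_error(accept_sample(make_calls(n_neg = 8), attempts = 3), "1 or 2")
})

test_that("overall genotype bins the positive-marker count", {
  expect_equal(overall_genotype(make_calls(n_neg = 10)), "negative")
  expect_equal(overall_genotype(make_calls(n_neg = 9, n_pos = 1)), "LOH-low")
  expect_equal(overall_genotype(make_calls(n_neg = 8, n_pos = 2)), "LOH-low")
  expect_equal(overall_genotype(make_calls(n_neg = 7, n_pos = 3)),
               "LOH-medium")
  expect_equal(overall_genotype(make_calls(n_neg = 6, n_pos = 4)),
               "LOH-medium")
  expect_equal(overall_genotype(make_calls(n_neg = 5, n_pos = 5)),
               "LOH-high")
})

test_that("calibration brackets 1, handles degeneracy, flags thin markers", {
  # noiseless panel: minimum width around 1
  panel0 <- generate_healthy_panel(20, cohort_spec(ratio_noise_sd = 0,
                                                   seed = 41))
  ct0 <- calibrate_cutoffs(panel0)
  expect_true(all(ct0$lower < 1 & ct0$upper > 1))
  expect_equal(ct0$lower, rep(exp(-0.05), nrow(ct0)), tolerance = 1e-6)
  expect_equal(ct0$upper, rep(exp(0.05), nrow(ct0)), tolerance = 1e-6)

  # noisy panel: cut-offs bracket 1
  ct <- calibrate_cutoffs(generate_healthy_panel(50, cohort_spec(seed = 42)))
  expect_true(all(ct$lower < 1 & 1 < ct$upper))

  # a marker with a single heterozygous pair is flagged, not emitted
  spec1 <- cohort_spec(n_markers = 2, het_rate = 1, seed = 43)
  panel <- generate_healthy_panel(5, spec1)
  hets_m2 <- panel$sample_id[panel$marker == "M02" &
                               panel$specimen == "blood"]
  keep_one <- names(which(table(hets_m2) > 0))[1]
  panel <- panel[!(panel$marker == "M02" & panel$sample_id != keep_one), ]
  ct1 <- calibrate_cutoffs(panel)
  expect_equal(attr(ct1, "flagged"), "M02")
  expect_false("M02" %in% ct1$marker)
})

test_that("about 0.3 percent of healthy loci escape 3-SD cut-offs", {
  # calibrate on one large panel, score an independent one
  ct <- calibrate_cutoffs(generate_healthy_panel(400, cohort_spec(seed = 51)),
                          min_log_width = 0)
  fresh <- generate_healthy_panel(400, cohort_spec(seed = 52))
  calls <- call_cohort(fresh, ct)
  informative <- calls$call %in% c("Negative", "Positive")
  fp <- mean(calls$call[informative] == "Positive")
  expect_gt(fp, 0.0002)
  expect_lt(fp, 0.01)
})

test_that("the positive-control gate passes and fails as specified", {
  ct <- cutoff_table("M01")
  expected <- data.frame(marker = "M01", allele_size = 150)
  good <- peak_rows("HL60", "blood", "M01", 150, 5000)
  expect_true(validate_positive_control(good, expected, ct)$pass)

  weak <- peak_rows("HL60", "blood", "M01", 150, 150)
  res <- validate_positive_control(weak, expected, ct)
  expect_false(res$pass)
  expect_match(res$reason, "RFU")

  off_size <- peak_rows("HL60", "blood", "M01", 153, 5000)
  expect_false(validate_positive_control(off_size, expected, ct)$pass)

  missing <- validate_positive_control(NULL, expected, ct)
  expect_false(missing$pass)
  expect_equal(missing$reason, "no control")
})

test_that("cut-off tables round-trip through YAML and JSON", {
  ct <- cutoff_table(c("M01", "M02"), lower = c(0.6, 0.55),
                     upper = c(1.7, 1.9), min_informative_loci = 7)
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_cutoff_table(ct, path)
    back <- read_cutoff_table(path)
    expect_equal(back$lower, ct$lower, tolerance = 1e-12)
    expect_equal(back$upper, ct$upper, tolerance = 1e-12)
    expect_equal(attr(back, "min_informative_loci"), 7)
  }
  expect_error(cutoff_table("M01", lower = 1.2), "lower")
})
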
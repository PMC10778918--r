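# Small builders for locus / call / profile fixtures used across tests.

# a consolidated locus object without going through a peak table
locus <- function(specimen, sizes, heights, sample = "S1", marker = "M01") {
  list(sample_id = sample, marker = marker, specimen = specimen,
       alleles = data.frame(size = sizes, height = heights))
}

# peak-table rows for one locus
peak_rows <- function(sample, specimen, marker, sizes, heights) {
  data.frame(sample_id = sample, specimen = specimen, marker = marker,
             allele_size = sizes, peak_height = heights,
             stringsAsFactors = FALSE)
}

# a calls data frame with given per-level counts, markers M01, M02, ...
make_calls <- function(n_neg = 0, n_pos = 0, n_ni = 0, n_ne = 0,
                       sample = "S1") {
  call <- c(rep("Negative", n_neg), rep("Positive", n_pos),
            rep("NonInformative", n_ni), rep("NonEvaluable", n_ne))
  n <- length(call)
  data.frame(sample_id = sample, marker = sprintf("M%02d", seq_len(n)),
             call = factor(call, levels = c("Negative", "Positive",
                                            "NonInformative",
                                            "NonEvaluable")),
             ratio = NA_real_, flag = "", stringsAsFactors = FALSE)
}

# brute-force AUC: concordant-pair count with half credit for ties
auc_bruteforce <- function(scores, labels, positive = "cancer") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# a separable two-class marker matrix: marker M01 equals the class
separable_matrix <- function(n_per_class = 30, n_noise = 4, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  status <- rep(c("cancer", "normal"), each = n_per_class)
  df <- data.frame(sample_id = sprintf("S%03d", seq_len(n)), status = status,
                   M01 = as.integer(status == "cancer"),
                   stringsAsFactors = FALSE)
  for (j in seq_len(n_noise)) {
    df[[sprintf("M%02d", j + 1)]] <- rbinom(n, 1, 0.5)
  }
  marker_matrix(df)
}
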
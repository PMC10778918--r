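# Pipeline stages: splitting, rebalancing, boosting, proximity outliers,
# permutation importance, one-class scorers and stacking.

test_that("splits are exhaustive, disjoint, seeded and train-favouring", {
  mm <- generate_marker_matrix(cohort_spec(n_cancer = 75, n_normal = 25,
                                           seed = 1))$matrix
  plan <- split_plan(n_splits = 3, master_seed = 2)
  splits <- split_data(mm, plan)
  expect_length(splits, 3)
  for (sp in splits) {
    expect_setequal(c(sp$train, sp$test), seq_len(100))
    expect_length(intersect(sp$train, sp$test), 0)
    expect_length(sp$train, 80)
    expect_length(sp$test, 20)
    # stratification preserves the 3:1 imbalance in both partitions
    expect_equal(sum(mm$status[sp$test] == "cancer"), 15)
  }
  again <- split_data(mm, plan)
  expect_identical(splits, again)

  # n = 5 with an 80/20 plan: rounding favours training -> 4/1
  tiny <- marker_matrix(data.frame(
    sample_id = letters[1:5], status = c("cancer", "cancer", "cancer",
                                         "normal", "normal"),
    M01 = c(1L, 1L, 0L, 0L, 0L)))
  sp5 <- split_data(tiny, split_plan(seeds = 7, stratified = FALSE))[[1]]
  expect_length(sp5$train, 4)
  expect_length(sp5$test, 1)

  single <- marker_matrix(data.frame(sample_id = letters[1:3],
                                     status = rep("cancer", 3),
                                     M01 = c(1L, 0L, 1L)))
  expect_error(split_data(single, plan), "single-class")
  expect_error(split_plan(seeds = c(1, 1)), "distinct")
  expect_error(split_plan(train_fraction = 1), "strictly between")
})

test_that("up-sampling equalises classes using only original minority rows", {
  mm <- generate_marker_matrix(cohort_spec(n_cancer = 180, n_normal = 60,
                                           seed = 3))$matrix
  up <- upsample_minority(mm, seed = 1)
  tab <- table(up$status)
  expect_equal(unname(tab[["cancer"]]), 180)
  expect_equal(unname(tab[["normal"]]), 180)
  # every added row duplicates an original minority sample
  expect_true(all(up$sample_id[up$status == "normal"] %in%
                    mm$sample_id[mm$status == "normal"]))
  # already balanced input is returned unchanged
  bal <- generate_marker_matrix(cohort_spec(n_cancer = 30, n_normal = 30,
                                            seed = 4))$matrix
  expect_identical(upsample_minority(bal, seed = 1), bal)
})

test_that("boosting separates separable data and respects contracts", {
  mm <- separable_matrix(n_per_class = 40, seed = 5)
  sp <- split_data(mm, split_plan(n_splits = 1, master_seed = 6))[[1]]
  fit <- fit_sgb(marker_matrix(mm[sp$train, ]), seed = 1)
  auc <- roc_auc(predict(fit, mm[sp$test, ]), mm$status[sp$test])$auc
  expect_equal(auc, 1.0)

  one_class <- marker_matrix(data.frame(sample_id = letters[1:6],
                                        status = rep("cancer", 6),
                                        M01 = rep(c(0L, 1L), 3)))
  expect_error(fit_sgb(one_class), "both cancer and normal")
  expect_error(sgb_params(learn_rate = 0), "learn_rate")
  expect_error(sgb_params(sample_size = 1.2), "sample_size")
})

test_that("constant predictors drive predictions to the class prevalence", {
  n <- 120
  df <- data.frame(sample_id = sprintf("S%03d", 1:n),
                   status = rep(c("cancer", "normal"), c(90, 30)),
                   M01 = 1L, M02 = 0L)
  mm <- marker_matrix(df)
  fit <- fit_sgb(mm, sgb_params(n_trees = 300), seed = 1)
  expect_equal(mean(predict(fit, mm)), 0.75, tolerance = 0.02)
})

test_that("tuning returns the sole grid point and breaks ties simply", {
  mm <- separable_matrix(n_per_class = 20, seed = 7)
  grid1 <- data.frame(tree_depth = 2, min_n = 5, loss_reduction = 0,
                      sample_size = 0.9, mtry = 2, learn_rate = 0.1)
  tuned <- tune_sgb(mm, grid = grid1, seed = 1)
  expect_equal(tuned$tree_depth, 2)
  expect_equal(tuned$learn_rate, 0.1)
  expect_error(tune_sgb(mm, grid = grid1[0, ]), "empty")

  # constant predictors: all settings tie at chance; simplest one wins
  const <- marker_matrix(data.frame(sample_id = sprintf("S%02d", 1:40),
                                    status = rep(c("cancer", "normal"), 20),
                                    M01 = 1L))
  grid2 <- data.frame(tree_depth = c(5, 1), min_n = 5, loss_reduction = 0,
                      sample_size = 1, mtry = 1, learn_rate = c(0.3, 0.05))
  best <- tune_sgb(const, grid = grid2, seed = 1)
  expect_equal(best$tree_depth, 1)
  expect_equal(best$learn_rate, 0.05)
})

test_that("proximity matrices are symmetric with unit diagonal in [0,1]", {
  mm <- generate_marker_matrix(cohort_spec(n_cancer = 40, n_normal = 20,
                                           seed = 8))$matrix
  prox <- rf_proximity(mm, ntree = 100, seed = 1)
  expect_equal(prox, t(prox))
  expect_equal(unname(diag(prox)), rep(1, nrow(mm)))
  expect_true(all(prox >= 0 & prox <= 1))
})

test_that("duplicated identical cases produce no outlier removals", {
  row_c <- c(1L, 1L, 0L, 1L, 0L)
  row_n <- c(0L, 0L, 1L, 0L, 0L)
  df <- data.frame(sample_id = sprintf("S%02d", 1:24),
                   status = rep(c("cancer", "normal"), each = 12),
                   rbind(matrix(rep(row_c, 12), 12, byrow = TRUE),
                         matrix(rep(row_n, 12), 12, byrow = TRUE)))
  names(df)[3:7] <- sprintf("M%02d", 1:5)
  out <- remove_outliers_rf(marker_matrix(df), ntree = 100, seed = 1)
  expect_length(out$removed, 0)
  expect_equal(nrow(out$matrix), 24)

  small <- marker_matrix(df[c(1:12, 13:17), ])
  expect_error(remove_outliers_rf(small), "per class")
})

test_that("permutation importance is zero for constants, K-invariant in
          expectation, and finds a planted predictor", {
  mm <- separable_matrix(n_per_class = 30, seed = 9)
  mm$M06 <- 1L  # constant column
  mm <- marker_matrix(as.data.frame(mm))
  fit <- fit_sgb(mm, seed = 1)
  imp <- permutation_importance(fit, mm, K = 20, seed = 2)
  expect_equal(imp$importance[imp$feature == "M06"], 0)
  expect_equal(imp$rank[imp$feature == "M01"], 1)
  expect_setequal(imp$rank, seq_len(nrow(imp)))
  expect_error(permutation_importance(fit, mm, K = 0), "K")

  # doubling K leaves the expected importance unchanged (Monte-Carlo)
  i_small <- mean(replicate(8, {
    permutation_importance(fit, mm, K = 10,
                           seed = sample.int(1e6, 1))$importance[1]
  }))
  i_large <- permutation_importance(fit, mm, K = 160, seed = 3)$importance[1]
  expect_lt(abs(i_small - i_large), 0.05)
})

test_that("top-k selection keeps the ranked markers and recomputes burden", {
  mm <- add_marker_count(separable_matrix(n_per_class = 30, seed = 10))
  fit <- fit_sgb(marker_matrix(
    mm[, setdiff(names(mm), "marker_count")]), seed = 1)
  imp <- permutation_importance(fit, mm, K = 30, seed = 1,
                                features = marker_columns(mm))
  all_k <- select_top_k(mm, imp, k = length(marker_columns(mm)))
  expect_setequal(marker_columns(all_k), marker_columns(mm))

  top2 <- select_top_k(mm, imp, k = 2)
  expect_length(marker_columns(top2), 2)
  expect_true("M01" %in% marker_columns(top2))
  expect_equal(top2$marker_count,
               unname(rowSums(top2[, marker_columns(top2)])))
  expect_error(select_top_k(mm, imp, k = 0), "positive")
  expect_error(select_top_k(mm, imp, k = 99), "exceeds")
})

test_that("one-class scorers separate inliers from far-out points", {
  set.seed(11)
  mm <- generate_marker_matrix(cohort_spec(n_cancer = 40, n_normal = 20,
                                           seed = 11))$matrix
  oc <- fit_one_class(mm, nu = 0.1)
  inlier <- mm[mm$status == "cancer", ][1, ]
  outlier <- inlier
  outlier[, marker_columns(mm)] <-
    as.list(100L + seq_along(marker_columns(mm)))
  s_in <- predict(oc, inlier)
  s_out <- predict(oc, outlier)
  expect_gt(s_in$cancer_score, s_out$cancer_score)
  # determinism: same query, same score
  expect_identical(predict(oc, inlier), predict(oc, inlier))

  few <- marker_matrix(data.frame(sample_id = letters[1:7],
                                  status = c(rep("cancer", 4),
                                             rep("normal", 3)),
                                  M01 = rep(c(1L, 0L), c(4, 3))))
  expect_error(fit_one_class(few), ">= 5 samples per class")
})

test_that("about nu of the training class falls outside its boundary", {
  set.seed(12)
  n <- 400
  # a tight continuous cluster per class; the scorer accepts any data
  # frame with status + feature columns
  df <- data.frame(sample_id = sprintf("S%03d", 1:n),
                   status = rep(c("cancer", "normal"), each = n / 2))
  for (j in 1:4) df[[sprintf("M%02d", j)]] <- rnorm(n)
  oc <- fit_one_class(df, nu = 0.2)
  cancer_rows <- df[df$status == "cancer", ]
  frac_out <- mean(predict(oc, cancer_rows)$cancer_score < 0)
  expect_equal(frac_out, 0.2, tolerance = 0.1)
})

test_that("the elastic-net stacker respects its contracts", {
  set.seed(13)
  n <- 200
  labels <- rep(c("cancer", "normal"), each = n / 2)
  feats <- data.frame(sgb_prob = ifelse(labels == "cancer", 0.9, 0.1) +
                        rnorm(n, 0, 0.05),
                      cancer_score = rnorm(n), normal_score = rnorm(n))
  expect_error(stack_models(feats, labels[-1]), "mismatched")
  fit <- stack_models(feats, labels, seed = 1)
  p <- predict(fit, feats)
  expect_true(all(p >= 0 & p <= 1))
  # monotone in the informative feature when the others are fixed
  grid <- data.frame(sgb_prob = seq(0, 1, 0.1), cancer_score = 0,
                     normal_score = 0)
  expect_true(all(diff(predict(fit, grid)) >= 0))

  # all-constant features: prediction collapses to the prevalence
  const <- data.frame(sgb_prob = 0.5, cancer_score = 1,
                      normal_score = 1)[rep(1, n), ]
  cfit <- stack_models(const, labels, seed = 1)
  expect_equal(predict(cfit, const[1:5, ]), rep(0.5, 5))
})

test_that("stacking a predictive model with noise scorers does not hurt", {
  set.seed(14)
  aucs <- replicate(20, {
    n <- 160
    labels <- rep(c("cancer", "normal"), each = n / 2)
    feats <- data.frame(
      sgb_prob = ifelse(labels == "cancer", 0.8, 0.2) + rnorm(n, 0, 0.15),
      cancer_score = rnorm(n), normal_score = rnorm(n))
    train <- seq_len(n) %% 2 == 0
    fit <- stack_models(feats[train, ], labels[train],
                        seed = sample.int(1e6, 1))
    c(stacked = roc_auc(predict(fit, feats[!train, ]),
                        labels[!train])$auc,
      alone = roc_auc(feats$sgb_prob[!train], labels[!train])$auc)
  })
  expect_gte(mean(aucs["stacked", ]), mean(aucs["alone", ]) - 0.02)
})
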
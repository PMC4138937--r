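make_pattern <- function(rois, z = NULL, modules = NULL) {
  k <- length(rois)
  structure(data.frame(index = seq_len(k), roi = rois,
                       module = modules %||% rep("sensorimotor", k),
                       z = z %||% rep(2.5, k),
                       n_pairs = rep(24L, k), degenerate = rep(FALSE, k),
                       stringsAsFactors = FALSE),
            criterion = selection_criterion("abs_gt"),
            class = c("discriminative_pattern", "data.frame"))
}

test_that("sample assembly: one sample per subject per condition", {
  set.seed(3)
  v <- matrix(runif(24 * 6), 24, 6)
  ec <- fake_table(v, "EC")
  eo <- fake_table(v + 0.1, "EO")
  pat <- make_pattern(c("roi_03", "roi_01"))
  s <- assemble_samples(ec, eo, pat)
  expect_equal(nrow(s$features), 48)
  expect_equal(ncol(s$features), 2)
  expect_identical(colnames(s$features), c("roi_03", "roi_01"))
  expect_equal(sum(s$labels == 1), 24)

  one <- assemble_samples(fake_table(v[1, , drop = FALSE], "EC"),
                          fake_table(v[1, , drop = FALSE] + 1, "EO"), pat)
  expect_equal(nrow(one$features), 2)
  expect_equal(sort(one$labels), c(-1, 1))

  empty <- make_pattern(character(0))
  expect_error(assemble_samples(ec, eo, empty), "empty")
})

test_that("per-condition half split is balanced, seeded and complementary", {
  v <- matrix(runif(24 * 4), 24, 4)
  s <- assemble_samples(fake_table(v, "EC"), fake_table(v, "EO"),
                        make_pattern("roi_02"))
  sp <- split_half(s, seed = 11)
  for (half in c("train", "test")) {
    expect_equal(sum(sp$split == half), 24)
    expect_equal(sum(sp$split == half & sp$labels == 1), 12)
  }
  expect_identical(split_half(s, 11)$split, sp$split)
  expect_false(identical(split_half(s, 12)$split, sp$split))
  expect_setequal(which(sp$split == "train"),
                  setdiff(seq_len(48), which(sp$split == "test")))

  odd <- assemble_samples(fake_table(v[1:5, ], "EC"),
                          fake_table(v[1:5, ], "EO"), make_pattern("roi_02"))
  expect_error(split_half(odd, 1), "even")
})

test_that("subject-stratified split keeps both recordings together", {
  v <- matrix(runif(12 * 3), 12, 3)
  s <- assemble_samples(fake_table(v, "EC"), fake_table(v, "EO"),
                        make_pattern("roi_01"))
  sp <- split_by_subject(s, 4)
  for (id in unique(sp$subject_ids))
    expect_length(unique(sp$split[sp$subject_ids == id]), 1)
})

test_that("linear SVM separates, concentrates weight, and is label symmetric", {
  set.seed(41)
  n <- 20
  feats <- cbind(c(rnorm(n, 2, 0.3), rnorm(n, -2, 0.3)),
                 matrix(rnorm(2 * n * 3, 0, 0.3), 2 * n, 3))
  colnames(feats) <- paste0("f", 1:4)
  s <- structure(list(features = feats, labels = rep(c(1, -1), each = n),
                      subject_ids = sprintf("s%02d", 1:(2 * n)),
                      condition = rep(c("EC", "EO"), each = n),
                      split = rep(NA_character_, 2 * n)),
                 class = "sample_set")
  m <- train_linear_svm(s)
  pred <- predict(m, feats)
  expect_equal(pred, s$labels)                      # separable: 100% training
  expect_gt(abs(m$w[1]), 5 * max(abs(m$w[-1])))     # informative axis dominates

  # compare against the exhaustive 1-D threshold oracle on the true axis
  cuts <- sort(feats[, 1])
  best_1d <- max(vapply(cuts, function(c0)
    mean((feats[, 1] >= c0) == (s$labels == 1)), numeric(1)))
  expect_gte(mean(pred == s$labels), best_1d - 1e-9)

  flipped <- s
  flipped$labels <- -s$labels
  m2 <- train_linear_svm(flipped)
  expect_equal(mean(predict(m2, feats) == flipped$labels),
               mean(pred == s$labels))
})

test_that("duplicated feature column barely moves the decision values", {
  set.seed(43)
  n <- 16
  feats <- cbind(c(rnorm(n, 1.5, 0.4), rnorm(n, -1.5, 0.4)),
                 rnorm(2 * n, 0, 0.4))
  s <- structure(list(features = feats, labels = rep(c(1, -1), each = n),
                      subject_ids = sprintf("s%02d", 1:(2 * n)),
                      condition = rep(c("EC", "EO"), each = n),
                      split = rep(NA_character_, 2 * n)),
                 class = "sample_set")
  m1 <- train_linear_svm(s)
  d1 <- decision_values(m1, feats)
  s2 <- s
  s2$features <- cbind(feats, feats[, 2])
  m2 <- train_linear_svm(s2)          # direct refit on the duplicated design
  d2 <- decision_values(m2, s2$features)
  expect_equal(sign(d1), sign(d2))
  expect_lt(max(abs(d1 - d2)), 0.25 * diff(range(d1)))
})

test_that("feature rescaling with matched regularization preserves predictions", {
  set.seed(47)
  n <- 14
  feats <- cbind(c(rnorm(n, 1, 0.5), rnorm(n, -1, 0.5)), rnorm(2 * n))
  s <- structure(list(features = feats, labels = rep(c(1, -1), each = n),
                      subject_ids = sprintf("s%02d", 1:(2 * n)),
                      condition = rep(c("EC", "EO"), each = n),
                      split = rep(NA_character_, 2 * n)),
                 class = "sample_set")
  base_pred <- predict(train_linear_svm(s, cost = 1), feats)
  for (c0 in c(0.1, 10)) {
    sc <- s
    sc$features <- feats * c0
    m <- train_linear_svm(sc, cost = 1 / c0^2)
    expect_equal(predict(m, sc$features), base_pred)
  }
})

test_that("evaluation: accuracy, ROC shape and AUC oracles", {
  labels <- rep(c(1, -1), each = 12)
  set.seed(52)
  roc <- roc_points(ifelse(labels == 1, 2, -2) + rnorm(24, 0, 0.1), labels)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))

  # constant decision values: one diagonal step, AUC 1/2
  roc_flat <- roc_points(rep(0.3, 24), labels)
  expect_equal(nrow(roc_flat), 2)
  expect_equal(falffdecode:::auc_trapezoid(roc_flat), 0.5)

  # AUC equals the Mann-Whitney pair-counting statistic
  set.seed(53)
  for (i in 1:25) {
    sc <- round(rnorm(20), 1)          # rounding forces ties
    lb <- sample(rep(c(1, -1), 10))
    expect_equal(falffdecode:::auc_trapezoid(roc_points(sc, lb)),
                 mann_whitney_auc(sc, lb), tolerance = 1e-12)
  }
})

test_that("end-to-end decoding on a separable synthetic study", {
  tabs <- quick_cohort_tables(n_subjects = 8, seed = 2, effect_size = 1.5)
  z <- score_all_rois(tabs$EC, tabs$EO, template = tabs$template)
  pat <- select_pattern(z, selection_criterion("abs_gt"))
  expect_gte(nrow(pat), 1)
  res <- decode_pattern(tabs$EC, tabs$EO, pat, split_seed = 6)
  expect_s3_class(res, "decoding_result")
  expect_true(res$accuracy >= 0 && res$accuracy <= 100)
  expect_equal(res$n_test, 8)
  expect_equal(res$auc,
               falffdecode:::auc_trapezoid(res$roc))

  # deterministic under fixed seeds
  res2 <- decode_pattern(tabs$EC, tabs$EO, pat, split_seed = 6)
  expect_identical(res$accuracy, res2$accuracy)
  expect_identical(res$decision_values, res2$decision_values)

  cmp <- run_criterion_comparison(tabs$EC, tabs$EO, z, split_seed = 6)
  expect_equal(nrow(cmp), 4)
  expect_true(all(cmp$n_regions[cmp$available] > 0))
  cmp2 <- run_criterion_comparison(tabs$EC, tabs$EO, z, split_seed = 6)
  expect_equal(cmp$accuracy, cmp2$accuracy)
})

test_that("single-class training refuses and nested audit runs", {
  v <- matrix(runif(12 * 3), 12, 3)
  s <- assemble_samples(fake_table(v, "EC"), fake_table(v + 0.2, "EO"),
                        make_pattern("roi_01"))
  s$labels <- rep(1, length(s$labels))
  expect_error(train_linear_svm(s), "both classes")

  tabs <- quick_cohort_tables(n_subjects = 12, seed = 5, effect_size = 1.5)
  res <- decode_nested(tabs$EC, tabs$EO, selection_criterion("abs_gt"),
                       split_seed = 3)
  expect_true(is.null(res) || inherits(res, "decoding_result"))
})
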
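test_that("signed-rank Z matches the closed form and its conventions", {
  # W+ = 15, Z = 7.5 / sqrt(13.75) for all-positive 1..5
  w <- wilcoxon_signed_rank_z(1:5)
  expect_equal(w$z, 7.5 / sqrt(13.75), tolerance = 1e-12)
  expect_equal(w$n_pairs, 5L)
  expect_false(w$degenerate)

  # antisymmetric paired magnitudes cancel
  expect_equal(wilcoxon_signed_rank_z(c(-3, -1, 1, 3, -5, 5))$z, 0)

  # exact zeros are dropped before ranking
  expect_equal(wilcoxon_signed_rank_z(c(0, 0, 1:5))$z,
               wilcoxon_signed_rank_z(1:5)$z)

  deg <- wilcoxon_signed_rank_z(rep(0, 6))
  expect_true(deg$degenerate)
  expect_equal(deg$z, 0)

  expect_error(wilcoxon_signed_rank_z(c(1, -2, 3, 4)), "fewer than 5")
  expect_error(wilcoxon_signed_rank_z(c(1, NA, 2, 3, 4)), "finite")
})

test_that("tie-corrected Z agrees with the tie-corrected normal test", {
  # stats::wilcox.test with exact = FALSE, correct = FALSE applies the same
  # midrank/tie-corrected variance; recover |Z| from its p value
  set.seed(31)
  for (i in 1:50) {
    d <- sample(c(-4:-1, 1:4), 12, replace = TRUE)
    z <- wilcoxon_signed_rank_z(d)$z
    if (abs(z) < 1e-12) next
    p <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = FALSE))$p.value
    expect_equal(abs(z), qnorm(p / 2, lower.tail = FALSE), tolerance = 1e-8)
  }
})

test_that("normal approximation tracks exact enumeration (mid-p) at n <= 12", {
  # bounds frozen from the enumeration oracle: <= 0.037 overall for n >= 5,
  # tightening to <= 0.03 from n = 7 up (|Z| <= 2.5 throughout)
  for (n in c(5, 6, 8)) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    gaps <- apply(signs, 1, function(s) {
      d <- s * seq_len(n)
      z <- wilcoxon_signed_rank_z(d)$z
      if (abs(z) > 2.5) return(0)
      abs(enumerate_signed_rank_midp(d) - 2 * pnorm(-abs(z)))
    })
    expect_lte(max(gaps), if (n >= 7) 0.03 else 0.037)
  }

  # the enumeration oracle also covers tied magnitudes, where discreteness
  # is heavier (bound frozen from the oracle at these draws)
  set.seed(7)
  for (i in 1:10) {
    d <- sample(c(-3:-1, 1:3), 9, replace = TRUE)
    z <- wilcoxon_signed_rank_z(d)$z
    if (abs(z) > 2.5 || abs(z) < 1e-12) next
    expect_lte(abs(enumerate_signed_rank_midp(d) - 2 * pnorm(-abs(z))), 0.06)
  }
})

test_that("ROI scoring pairs by subject id and is antisymmetric", {
  set.seed(17)
  v_ec <- matrix(rexp(6 * 5) + 0.5, 6, 5)
  v_eo <- matrix(rexp(6 * 5) + 0.5, 6, 5)
  ec <- fake_table(v_ec, "EC")
  eo <- fake_table(v_eo, "EO")
  z <- score_all_rois(ec, eo)
  expect_s3_class(z, "roi_zscores")
  expect_equal(nrow(z), 5)

  # identical tables: all degenerate zeros
  z0 <- score_all_rois(ec, fake_table(v_ec, "EO"))
  expect_true(all(z0$degenerate))
  expect_equal(z0$z, rep(0, 5))

  # swapping condition roles negates every Z
  z_swap <- score_all_rois(eo, ec)
  expect_equal(z_swap$z, -z$z)

  # pairing is by id, not by row order
  perm <- c(3, 1, 2, 6, 5, 4)
  eo_shuffled <- fake_table(v_eo[perm, ], "EO",
                            subject_ids = ec$subject_ids[perm])
  expect_equal(score_all_rois(ec, eo_shuffled)$z, z$z)

  bad <- fake_table(v_eo, "EO", subject_ids = sprintf("other-%d", 1:6))
  expect_error(score_all_rois(ec, bad), "sub-01")
})

test_that("reference pattern selection reproduces the published counts", {
  z <- zscores_from_template(reference_regions())
  crit <- study_criteria()
  sizes <- vapply(crit, function(cr) nrow(select_pattern(z, cr)), integer(1))
  expect_equal(unname(sizes), c(28L, 21L, 13L, 7L))

  pos <- select_pattern(z, crit$pos_gt)
  comp <- module_composition(pos)
  expect_equal(comp$n[comp$module == "sensorimotor"], 18)
  expect_equal(round(comp$percent[comp$module == "sensorimotor"]), 86)
  expect_equal(sum(module_composition(select_pattern(z, crit$abs_gt))$n), 28)

  # ordering: descending |Z|, ties by template order
  expect_true(all(diff(abs(pos$z)) <= 0))
  tied <- pos[abs(pos$z - 2.92) < 1e-9, ]
  expect_equal(tied$index, sort(tied$index))
})

test_that("selection criteria nest and split as set identities", {
  set.seed(23)
  for (i in 1:20) {
    z <- structure(data.frame(index = 1:40, roi = sprintf("r%02d", 1:40),
                              z = rnorm(40, 0, 1.8), n_pairs = 24L,
                              degenerate = FALSE),
                   class = c("roi_zscores", "data.frame"))
    crit <- study_criteria()
    p_abs <- suppressWarnings(select_pattern(z, crit$abs_gt))$index
    p_pos <- suppressWarnings(select_pattern(z, crit$pos_gt))$index
    p_str <- suppressWarnings(select_pattern(z, crit$pos_gt_strict))$index
    p_neg <- suppressWarnings(select_pattern(z, crit$neg_lt))$index
    expect_true(all(p_str %in% p_pos))
    expect_true(all(p_pos %in% p_abs))
    expect_setequal(p_abs, c(p_pos, p_neg))
    expect_length(intersect(p_pos, p_neg), 0)

    # antisymmetry: negating Z maps the positive pattern onto the negative
    z_neg <- z; z_neg$z <- -z$z
    expect_setequal(suppressWarnings(select_pattern(z_neg, crit$neg_lt))$index,
                    p_pos)
  }
})

test_that("degenerate selections warn and module composition guards", {
  z <- structure(data.frame(index = 1:4, roi = letters[1:4],
                            module = rep("default", 4),
                            z = c(0.1, -0.3, 0.2, 0.5), n_pairs = 24L,
                            degenerate = FALSE),
                 class = c("roi_zscores", "data.frame"))
  expect_warning(p <- select_pattern(z, selection_criterion("pos_gt")),
                 "selects no ROIs")
  expect_equal(nrow(p), 0)
  expect_error(module_composition(p), "empty")

  z$z[2] <- 3
  single <- select_pattern(z, selection_criterion("abs_gt"))
  comp <- module_composition(single)
  expect_equal(comp$percent, 100)
})
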
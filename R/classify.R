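# Linear SVM decoding of the EC/EO state from discriminative fALFF patterns.
#
# Samples are one row per subject per condition, labelled EC = +1, EO = -1.
# Following the study procedure, the samples of each condition are randomly
# halved into train/test (so one subject's two recordings may land in
# different halves); a subject-stratified split and a nested (selection
# inside the training half) audit mode are provided as alternatives.

#' Assemble labelled samples from two condition tables and a pattern
#'
#' @param table_ec,table_eo `falff_table`s with matching subjects.
#' @param pattern a non-empty `discriminative_pattern`; feature columns are
#'   taken in pattern order.
#' @return A `sample_set`: list with `features` (2n x k matrix), `labels`
#'   (+1 EC / -1 EO), `subject_ids`, `condition`, and `split` (NA until
#'   [split_half()] assigns one).
#' @export
assemble_samples <- function(table_ec, table_eo, pattern) {
  stopifnot(inherits(table_ec, "falff_table"), inherits(table_eo, "falff_table"),
            inherits(pattern, "discriminative_pattern"))
  assert_that(nrow(pattern) > 0,
              "empty discriminative pattern: nothing to classify on")
  assert_that(setequal(table_ec$subject_ids, table_eo$subject_ids),
              "subject sets differ between conditions")
  cols <- pattern$roi
  assert_that(all(cols %in% table_ec$roi_names),
              "pattern ROIs missing from feature tables")
  ids <- table_ec$subject_ids
  feats <- rbind(table_ec$values[ids, cols, drop = FALSE],
                 table_eo$values[ids, cols, drop = FALSE])
  structure(list(features = feats,
                 labels = rep(c(1, -1), each = length(ids)),
                 subject_ids = c(ids, ids),
                 condition = rep(c("EC", "EO"), each = length(ids)),
                 split = rep(NA_character_, 2 * length(ids))),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("Sample set: %d samples x %d features (%d EC / %d EO)%s\n",
              nrow(x$features), ncol(x$features),
              sum(x$labels == 1), sum(x$labels == -1),
              if (all(is.na(x$split))) "" else
                sprintf("; split %d train / %d test",
                        sum(x$split == "train"), sum(x$split == "test"))))
  invisible(x)
}

#' Random half split, per condition
#'
#' Randomly divides the samples of each condition into equal train and test
#' halves (the study scheme: a subject's EC and EO samples may land in
#' different halves). Deterministic under `seed`.
#'
#' @param samples a `sample_set`.
#' @param seed integer split seed.
#' @return The `sample_set` with `split` filled with "train"/"test".
#' @export
split_half <- function(samples, seed) {
  stopifnot(inherits(samples, "sample_set"))
  split <- rep(NA_character_, length(samples$labels))
  seeds <- derive_seeds(seed, 2)
  for (i in c(1, 2)) {
    idx <- which(samples$labels == c(1, -1)[i])
    assert_that(length(idx) %% 2 == 0,
                "per-condition sample count must be even to halve")
    tr <- with_seed(seeds[i], sample(idx, length(idx) / 2))
    split[tr] <- "train"
    split[setdiff(idx, tr)] <- "test"
  }
  samples$split <- split
  samples
}

#' Subject-stratified half split
#'
#' Alternative split that keeps both recordings of a subject in the same
#' half, so no subject identity leaks from train to test. Used by the
#' nested-selection audit mode.
#'
#' @inheritParams split_half
#' @export
split_by_subject <- function(samples, seed) {
  stopifnot(inherits(samples, "sample_set"))
  ids <- unique(samples$subject_ids)
  assert_that(length(ids) %% 2 == 0,
              "subject count must be even to halve by subject")
  tr_ids <- with_seed(seed, sample(ids, length(ids) / 2))
  samples$split <- ifelse(samples$subject_ids %in% tr_ids, "train", "test")
  samples
}

subset_samples <- function(samples, which_split) {
  keep <- samples$split == which_split
  list(features = samples$features[keep, , drop = FALSE],
       labels = samples$labels[keep],
       subject_ids = samples$subject_ids[keep])
}

#' Train a linear soft-margin SVM
#'
#' Fits a linear support-vector classifier (LIBSVM via e1071) at the given
#' regularization and extracts the primal weight vector and bias, giving the
#' decision function d(x) = w.x + b with d > 0 predicting EC (+1). Features
#' are not standardised (matching the study procedure); ties at d = 0
#' predict EC.
#'
#' @param samples a `sample_set`; if a split is assigned only the training
#'   half is used, otherwise all samples.
#' @param cost soft-margin regularization parameter C (default 1, the
#'   toolbox default).
#' @return A `linear_svm`: list with `w`, `b`, `cost` and the underlying fit.
#' @export
train_linear_svm <- function(samples, cost = 1) {
  stopifnot(inherits(samples, "sample_set"))
  tr <- if (all(is.na(samples$split))) samples else subset_samples(samples, "train")
  assert_that(length(unique(tr$labels)) == 2,
              "training data must contain both classes")
  y <- factor(tr$labels, levels = c(1, -1))
  fit <- e1071::svm(x = tr$features, y = y, kernel = "linear",
                    cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # e1071 orients the decision function toward the first factor level (+1);
  # guard against the opposite orientation all the same.
  dv <- drop(tr$features %*% w) + b
  pred_lab <- predict(fit, tr$features)
  agree <- mean((dv >= 0) == (pred_lab == "1"))
  if (agree < 0.5) {
    w <- -w
    b <- -b
  }
  structure(list(w = w, b = b, cost = cost, fit = fit),
            class = "linear_svm")
}

#' Decision values of a linear SVM
#' @param object a `linear_svm`.
#' @param features samples x features matrix.
#' @param ... unused.
#' @return Numeric decision values; `sign(d)` (with 0 mapped to +1) is the
#'   predicted label.
#' @export
decision_values <- function(object, features) {
  stopifnot(inherits(object, "linear_svm"))
  drop(features %*% object$w) + object$b
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  ifelse(decision_values(object, newdata) >= 0, 1, -1)
}

#' Empirical ROC curve from decision values
#'
#' Sweeps the decision threshold over the observed values (tied values form
#' a single step), producing a monotone curve from (0,0) to (1,1).
#'
#' @param scores numeric decision values (larger = more EC-like).
#' @param labels true labels, +1/-1.
#' @return data.frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  assert_that(length(scores) == length(labels) && length(scores) > 0,
              "scores and labels must be equal-length and non-empty")
  pos <- sum(labels == 1)
  neg <- sum(labels == -1)
  assert_that(pos > 0 && neg > 0, "both classes needed for an ROC curve")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  is_pos <- labels[o] == 1
  grp_end <- cumsum(rle(s)$lengths)
  data.frame(fpr = c(0, cumsum(!is_pos)[grp_end] / neg),
             tpr = c(0, cumsum(is_pos)[grp_end] / pos))
}

auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' Evaluate a trained decoder on the test half
#'
#' @param model a `linear_svm`.
#' @param samples a split `sample_set` (the "test" half is scored), or an
#'   unsplit set (all samples scored).
#' @param pattern optional pattern reference stored in the result.
#' @param split_seed optional seed recorded for provenance.
#' @return A `decoding_result`: list with `accuracy` (percent correct),
#'   `decision_values`, `roc` (fpr/tpr points), `auc`, `n_test`,
#'   `pattern_used`, `split_seed`.
#' @export
evaluate_decoding <- function(model, samples, pattern = NULL,
                              split_seed = NA_integer_) {
  stopifnot(inherits(model, "linear_svm"), inherits(samples, "sample_set"))
  te <- if (all(is.na(samples$split))) samples else subset_samples(samples, "test")
  assert_that(length(te$labels) > 0, "empty test set")
  dv <- decision_values(model, te$features)
  pred <- ifelse(dv >= 0, 1, -1)
  roc <- roc_points(dv, te$labels)
  structure(list(accuracy = 100 * mean(pred == te$labels),
                 decision_values = dv, labels = te$labels,
                 roc = roc, auc = auc_trapezoid(roc),
                 n_test = length(te$labels),
                 pattern_used = pattern, split_seed = split_seed),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("Decoding result: accuracy %.1f%% on %d test samples, AUC %.3f\n",
              x$accuracy, x$n_test, x$auc))
  invisible(x)
}

#' Decode one pattern end to end
#'
#' Convenience wrapper: assemble samples, split per condition, train, test.
#'
#' @param table_ec,table_eo `falff_table`s.
#' @param pattern a `discriminative_pattern`.
#' @param split_seed integer seed for the half split.
#' @param cost SVM regularization.
#' @param stratify_by_subject use [split_by_subject()] instead of the
#'   study's per-condition split.
#' @return A `decoding_result`.
#' @export
decode_pattern <- function(table_ec, table_eo, pattern, split_seed = 1,
                           cost = 1, stratify_by_subject = FALSE) {
  samples <- assemble_samples(table_ec, table_eo, pattern)
  samples <- if (stratify_by_subject) split_by_subject(samples, split_seed)
             else split_half(samples, split_seed)
  model <- train_linear_svm(samples, cost = cost)
  evaluate_decoding(model, samples, pattern = pattern, split_seed = split_seed)
}

#' Nested-selection decoding audit
#'
#' Quantifies the circularity of whole-cohort feature selection: subjects
#' are split in half first (subject-stratified), the signed-rank Z scores
#' and the pattern are computed from the training subjects only, and the
#' decoder is evaluated on the held-out subjects. Under a null cohort this
#' procedure is calibrated at chance, unlike selection on all subjects.
#'
#' @param table_ec,table_eo `falff_table`s.
#' @param criterion a [selection_criterion()].
#' @param split_seed integer seed.
#' @param cost SVM regularization.
#' @param template optional template for module labels.
#' @return A `decoding_result`, or `NULL` when the training-half selection
#'   is empty.
#' @export
decode_nested <- function(table_ec, table_eo, criterion, split_seed = 1,
                          cost = 1, template = NULL) {
  ids <- table_ec$subject_ids
  assert_that(length(ids) %% 2 == 0, "subject count must be even")
  tr_ids <- with_seed(split_seed, sample(ids, length(ids) / 2))
  take <- function(tab, keep) {
    structure(list(values = tab$values[keep, , drop = FALSE],
                   condition = tab$condition, subject_ids = keep,
                   roi_names = tab$roi_names), class = "falff_table")
  }
  z_tr <- score_all_rois(take(table_ec, tr_ids), take(table_eo, tr_ids),
                         template = template)
  pattern <- suppressWarnings(select_pattern(z_tr, criterion))
  if (nrow(pattern) == 0) return(NULL)
  te_ids <- setdiff(ids, tr_ids)
  samples <- assemble_samples(take(table_ec, te_ids), take(table_eo, te_ids),
                              pattern)
  model_samples <- assemble_samples(take(table_ec, tr_ids),
                                    take(table_eo, tr_ids), pattern)
  model <- train_linear_svm(model_samples, cost = cost)
  evaluate_decoding(model, samples, pattern = pattern, split_seed = split_seed)
}

#' Compare decoding across the four selection criteria
#'
#' Selects a pattern under each criterion from whole-cohort Z scores (the
#' study procedure), decodes each, and tabulates accuracy and AUC. With
#' `n_repeats > 1` the split is redrawn and means are reported.
#'
#' @param table_ec,table_eo `falff_table`s.
#' @param z whole-cohort `roi_zscores`.
#' @param criteria list of [selection_criterion()]s (default
#'   [study_criteria()]).
#' @param split_seed integer seed (repeat seeds are derived from it).
#' @param cost SVM regularization.
#' @param n_repeats number of random splits to average over (default 1,
#'   the single split of the study procedure).
#' @return data.frame with one row per criterion: `criterion`, `n_regions`,
#'   `accuracy`, `auc`, `available` (FALSE for empty patterns, whose
#'   metrics are NA); per-run results in the `runs` attribute.
#' @export
run_criterion_comparison <- function(table_ec, table_eo, z,
                                     criteria = study_criteria(),
                                     split_seed = 1, cost = 1,
                                     n_repeats = 1) {
  seeds <- derive_seeds(split_seed, n_repeats)
  runs <- list()
  rows <- lapply(names(criteria), function(nm) {
    pattern <- suppressWarnings(select_pattern(z, criteria[[nm]]))
    if (nrow(pattern) == 0)
      return(data.frame(criterion = criteria[[nm]]$label, n_regions = 0L,
                        accuracy = NA_real_, auc = NA_real_,
                        available = FALSE, stringsAsFactors = FALSE))
    res <- lapply(seeds, function(s)
      decode_pattern(table_ec, table_eo, pattern, split_seed = s, cost = cost))
    runs[[nm]] <<- res
    data.frame(criterion = criteria[[nm]]$label, n_regions = nrow(pattern),
               accuracy = mean(vapply(res, `[[`, numeric(1), "accuracy")),
               auc = mean(vapply(res, `[[`, numeric(1), "auc")),
               available = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(criteria)
  attr(out, "runs") <- runs
  out
}
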
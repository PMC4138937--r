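# Paired Wilcoxon signed-rank feature selection.
#
# For each ROI, the per-subject EC - EO fALFF differences are ranked by
# absolute value (midranks for ties, exact zeros dropped) and the positive
# rank sum W+ is standardised against its null mean n(n+1)/4 and
# tie-corrected variance n(n+1)(2n+1)/24 - sum(t^3 - t)/48. The sign
# convention is positive Z when EC exceeds EO. No continuity correction.

#' Signed-rank Z for one vector of paired differences
#'
#' @param d numeric vector of per-subject paired differences (EC - EO).
#' @return List with `z` (signed standard-normal deviate), `n_pairs`
#'   (non-zero differences used) and `degenerate` (TRUE when all
#'   differences are exactly zero, in which case `z = 0`).
#' @details Requires at least 5 non-zero differences: below that the normal
#'   approximation underlying the Z score is invalid and the function
#'   errors rather than report a meaningless deviate.
#' @export
wilcoxon_signed_rank_z <- function(d) {
  assert_that(is.numeric(d) && all(is.finite(d)),
              "differences must be finite numerics")
  d <- d[d != 0]
  if (length(d) == 0)
    return(list(z = 0, n_pairs = 0L, degenerate = TRUE))
  n <- length(d)
  assert_that(n >= 5,
              "fewer than 5 non-zero pairs: normal approximation invalid")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / 48
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - tie_corr
  list(z = (w_pos - mu) / sqrt(sigma2), n_pairs = n, degenerate = FALSE)
}

#' Score every ROI with a paired signed-rank Z
#'
#' Pairs the two condition tables by subject id (never by row position),
#' forms per-subject EC - EO differences for each ROI, and standardises.
#'
#' @param table_ec,table_eo `falff_table`s for the two conditions with
#'   identical subject sets and identical ROI ordering.
#' @param template optional [roi_template()] supplying module labels.
#' @return A `roi_zscores` data.frame with columns `index`, `roi`,
#'   (`module`,) `z`, `n_pairs`, `degenerate`.
#' @export
score_all_rois <- function(table_ec, table_eo, template = NULL) {
  stopifnot(inherits(table_ec, "falff_table"), inherits(table_eo, "falff_table"))
  assert_that(identical(table_ec$roi_names, table_eo$roi_names),
              "ROI names/order differ between the two condition tables")
  missing_ec <- setdiff(table_eo$subject_ids, table_ec$subject_ids)
  missing_eo <- setdiff(table_ec$subject_ids, table_eo$subject_ids)
  assert_that(length(missing_ec) + length(missing_eo) == 0,
              paste0("unpaired subjects - missing in EC: [",
                     paste(missing_ec, collapse = ", "), "], missing in EO: [",
                     paste(missing_eo, collapse = ", "), "]"))
  eo <- table_eo$values[table_ec$subject_ids, , drop = FALSE]
  diffs <- table_ec$values - eo
  res <- lapply(seq_len(ncol(diffs)),
                function(j) wilcoxon_signed_rank_z(diffs[, j]))
  out <- data.frame(index = seq_along(res),
                    roi = table_ec$roi_names,
                    z = vapply(res, `[[`, numeric(1), "z"),
                    n_pairs = vapply(res, `[[`, integer(1), "n_pairs"),
                    degenerate = vapply(res, `[[`, logical(1), "degenerate"),
                    stringsAsFactors = FALSE)
  if (!is.null(template)) {
    assert_that(nrow(template) == nrow(out),
                "template length does not match number of ROIs")
    out$module <- template$module
    out <- out[, c("index", "roi", "module", "z", "n_pairs", "degenerate")]
  }
  rownames(out) <- NULL
  class(out) <- c("roi_zscores", "data.frame")
  out
}

#' Build a `roi_zscores` object from already-known Z values
#'
#' Used to feed published Z values (e.g. the built-in 28-region reference
#' pattern, which carries a `z_value` column) straight into pattern
#' selection, skipping simulation and fALFF estimation.
#'
#' @param template a [roi_template()] with a `z_value` column, or any
#'   data.frame with `name`/`roi`, `z`/`z_value` and optionally `module`.
#' @return A `roi_zscores` data.frame.
#' @export
zscores_from_template <- function(template) {
  z <- template$z_value %||% template$z
  assert_that(!is.null(z), "no z_value / z column found")
  out <- data.frame(index = seq_len(nrow(template)),
                    roi = template$name %||% template$roi,
                    z = as.numeric(z),
                    n_pairs = NA_integer_, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(template$module)) {
    out$module <- template$module
    out <- out[, c("index", "roi", "module", "z", "n_pairs", "degenerate")]
  }
  class(out) <- c("roi_zscores", "data.frame")
  out
}

#' A feature-selection criterion on signed-rank Z scores
#'
#' The study's four criteria are `abs_gt` (|Z| > 1.96), `pos_gt`
#' (Z > 1.96), `pos_gt_strict` (Z > 2.25) and `neg_lt` (Z < -1.96); all
#' inequalities are strict.
#'
#' @param name one of `"abs_gt"`, `"pos_gt"`, `"pos_gt_strict"`, `"neg_lt"`.
#' @param threshold standard-normal threshold; defaults to the study value
#'   for the given name (1.96 / 1.96 / 2.25 / 1.96).
#' @return A `selection_criterion` list with a `label` and a predicate.
#' @export
selection_criterion <- function(name = c("abs_gt", "pos_gt", "pos_gt_strict",
                                         "neg_lt"),
                                threshold = NULL) {
  name <- match.arg(name)
  threshold <- threshold %||% switch(name, pos_gt_strict = 2.25, 1.96)
  assert_that(is.numeric(threshold) && threshold > 0,
              "threshold must be a positive number")
  label <- switch(name,
                  abs_gt = sprintf("|Z| > %.2f", threshold),
                  pos_gt = , pos_gt_strict = sprintf("Z > %.2f", threshold),
                  neg_lt = sprintf("Z < -%.2f", threshold))
  predicate <- switch(name,
                      abs_gt = function(z) abs(z) > threshold,
                      pos_gt = , pos_gt_strict = function(z) z > threshold,
                      neg_lt = function(z) z < -threshold)
  structure(list(name = name, threshold = threshold, label = label,
                 predicate = predicate),
            class = "selection_criterion")
}

#' The four study selection criteria
#'
#' @return Named list of [selection_criterion()]s: |Z| > 1.96, Z > 1.96,
#'   Z > 2.25, Z < -1.96.
#' @export
study_criteria <- function() {
  list(abs_gt = selection_criterion("abs_gt"),
       pos_gt = selection_criterion("pos_gt"),
       pos_gt_strict = selection_criterion("pos_gt_strict"),
       neg_lt = selection_criterion("neg_lt"))
}

#' Select a discriminative pattern under one criterion
#'
#' Applies the strict threshold filter and orders the surviving ROIs by
#' descending |Z|, ties broken by template order, giving a deterministic
#' feature vector.
#'
#' @param z a `roi_zscores` object from [score_all_rois()] or
#'   [zscores_from_template()].
#' @param criterion a [selection_criterion()].
#' @return A `discriminative_pattern`: data.frame of the selected rows with
#'   the criterion attached as an attribute. An empty selection is returned
#'   (with a warning); the classifier stage refuses empty patterns.
#' @export
select_pattern <- function(z, criterion) {
  stopifnot(inherits(z, "roi_zscores"), inherits(criterion, "selection_criterion"))
  keep <- which(criterion$predicate(z$z))
  out <- as.data.frame(z)[keep, , drop = FALSE]
  out <- out[order(-abs(out$z), out$index), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0)
    warning("criterion ", criterion$label, " selects no ROIs", call. = FALSE)
  structure(out, criterion = criterion,
            class = c("discriminative_pattern", "data.frame"))
}

#' @export
print.discriminative_pattern <- function(x, ...) {
  cr <- attr(x, "criterion")
  cat(sprintf("Discriminative pattern [%s]: %d ROI(s)\n", cr$label, nrow(x)))
  if (nrow(x)) print(as.data.frame(x))
  invisible(x)
}

#' Module composition of a pattern
#'
#' @param pattern a non-empty `discriminative_pattern` carrying a `module`
#'   column.
#' @return data.frame with per-module `n` and `percent` (counts sum to the
#'   pattern size; percentages to 100).
#' @export
module_composition <- function(pattern) {
  stopifnot(inherits(pattern, "discriminative_pattern"))
  assert_that(nrow(pattern) > 0, "pattern is empty")
  assert_that(!is.null(pattern$module), "pattern has no module labels")
  tab <- table(factor(pattern$module, levels = MODULE_LEVELS))
  tab <- tab[tab > 0]
  out <- data.frame(module = names(tab), n = as.integer(tab),
                    percent = 100 * as.integer(tab) / nrow(pattern),
                    stringsAsFactors = FALSE)
  out[order(-out$n), , drop = FALSE]
}
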
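# Shared fixtures and independent oracles, built in code at test time.

# A tiny template with a controllable module mix.
small_template <- function(n = 6, modules = NULL, spacing = 30) {
  modules <- modules %||% rep(MODULE_LEVELS, length.out = n)
  roi_template(data.frame(
    name = sprintf("roi_%02d", seq_len(n)),
    hem = rep(c("L", "R"), length.out = n),
    x = ifelse(seq_len(n) %% 2 == 1, -1, 1) * (20 + spacing * (seq_len(n) - 1)),
    y = rep(0, n), z = rep(0, n),
    module = modules, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wrap a plain subjects x ROI matrix as a feature table.
fake_table <- function(values, condition, subject_ids = NULL) {
  subject_ids <- subject_ids %||% sprintf("sub-%02d", seq_len(nrow(values)))
  rownames(values) <- subject_ids
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("roi_%02d", seq_len(ncol(values)))
  structure(list(values = values, condition = condition,
                 subject_ids = subject_ids, roi_names = colnames(values)),
            class = "falff_table")
}

# Exact two-sided mid-p of the signed-rank statistic by full enumeration of
# the 2^n sign assignments of |d| (midranks, so tied magnitudes are handled).
# Independent of the package's Z computation.
enumerate_signed_rank_midp <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- as.vector(signs %*% r)
  up <- mean(w_all > w_obs) + 0.5 * mean(w_all == w_obs)
  lo <- mean(w_all < w_obs) + 0.5 * mean(w_all == w_obs)
  min(1, 2 * min(up, lo))
}

# AUC as the Mann-Whitney pair-counting statistic (ties count one half).
mann_whitney_auc <- function(scores, labels) {
  s_pos <- scores[labels == 1]
  s_neg <- scores[labels == -1]
  pairs <- outer(s_pos, s_neg, `-`)
  mean((pairs > 0) + 0.5 * (pairs == 0))
}

# Small calibrated synthetic study shared by tests.
quick_cohort_tables <- function(n_subjects = 8, seed = 1, effect_size = 1,
                                template = small_template(12),
                                effect_rois = 1:3, n_volumes = 120, ...) {
  cfg <- sim_config(n_subjects = n_subjects, n_volumes = n_volumes,
                    effect_rois = effect_rois, effect_size = effect_size,
                    seed = seed, ...)
  cohort <- simulate_cohort(cfg, template)
  list(config = cfg, template = template,
       EC = falff_feature_table(cohort, "EC", n_discard = cfg$n_discard),
       EO = falff_feature_table(cohort, "EO", n_discard = cfg$n_discard))
}
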
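# End-to-end orchestration: simulate -> trim/detrend/fALFF -> signed-rank Z
# -> pattern selection -> split/train/evaluate, with TSV artifacts and a log.

#' Full run configuration
#'
#' @param simulation a [sim_config()].
#' @param bands a [spectral_bands()] (default derived from the simulation TR).
#' @param roi_radius sphere radius in mm (volumetric mode).
#' @param criteria list of [selection_criterion()]s (default the four study
#'   criteria).
#' @param svm_cost SVM regularization parameter.
#' @param split_seed seed for the train/test half split.
#' @param output_dir directory for artifacts (created if missing).
#' @param mode `"roi"` (default) or `"volumetric"`.
#' @param template template source for [load_roi_template()].
#' @return A validated `run_config` list.
#' @export
run_config <- function(simulation = sim_config(), bands = NULL,
                       roi_radius = 5, criteria = study_criteria(),
                       svm_cost = 1, split_seed = 1,
                       output_dir = tempfile("falffdecode-run-"),
                       mode = c("roi", "volumetric"),
                       template = "synthetic160") {
  mode <- match.arg(mode)
  stopifnot(inherits(simulation, "sim_config"))
  bands <- bands %||% spectral_bands(simulation$tr)
  structure(list(simulation = simulation, bands = bands,
                 roi_radius = roi_radius, criteria = criteria,
                 svm_cost = svm_cost, split_seed = as.integer(split_seed),
                 output_dir = output_dir, mode = mode, template = template),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The file mirrors the [run_config()] / [sim_config()] fields:
#' a top-level `simulation` mapping plus any of `roi_radius`, `svm_cost`,
#' `split_seed`, `output_dir`, `mode`, `template` and a `bands` mapping with
#' `low` (two numbers). Missing fields take the defaults.
#'
#' @param path YAML file path.
#' @param ... overrides applied after the file (e.g. `output_dir = ...`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$simulation %||% list())
  bands <- if (!is.null(y$bands))
    spectral_bands(sim$tr, low = as.numeric(y$bands$low %||% c(0.01, 0.08)))
  args <- list(simulation = sim, bands = bands)
  for (f in c("roi_radius", "svm_cost", "split_seed", "output_dir", "mode",
              "template"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  args <- modifyList(args, list(...))
  do.call(run_config, args)
}

provenance_lines <- function(config) {
  c(paste0("falffdecode ", as.character(utils::packageVersion("falffdecode"))),
    sprintf("simulation seed: %d; split seed: %d; subjects: %d; tr: %g",
            config$simulation$seed, config$split_seed,
            config$simulation$n_subjects, config$simulation$tr))
}

#' Run the full decoding pipeline
#'
#' Executes every stage in order: simulate the cohort, discard the first
#' `n_discard` volumes, detrend, compute normalised per-ROI fALFF tables for
#' EC and EO, score each ROI with the paired signed-rank Z, select a
#' discriminative pattern under each criterion, split samples per condition,
#' train the linear SVM and evaluate accuracy/ROC on the held-out half.
#' Writes a frozen YAML copy of the configuration, the feature tables, a
#' Z-score report with per-criterion selection flags, per-criterion pattern
#' and ROC TSVs, a results table, and a log. TSV artifacts are byte-stable
#' across reruns of the same configuration.
#'
#' @param config a [run_config()].
#' @param quiet suppress console logging.
#' @return The run manifest: list with `config`, `template`, `zscores`,
#'   `results` (per-criterion table), `artifacts` (named file paths).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  say <- function(...) {
    msg <- sprintf(...)
    writeLines(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), msg), log_con)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    say("stage %s: start", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  say("falffdecode pipeline, R %s", getRversion())
  prov <- provenance_lines(config)
  artifacts <- c(config = file.path(config$output_dir, "config.yaml"))
  yaml::write_yaml(list(
    simulation = unclass(config$simulation),
    bands = list(low = config$bands$low, full = config$bands$full),
    roi_radius = config$roi_radius, svm_cost = config$svm_cost,
    split_seed = config$split_seed, mode = config$mode,
    template = config$template), artifacts[["config"]])

  template <- stage("template", load_roi_template(config$template,
                                                  radius = config$roi_radius))
  cohort <- stage("simulate", simulate_cohort(config$simulation, template))
  say("simulated %d recordings (%d subjects x 2 conditions)",
      length(cohort), config$simulation$n_subjects)

  tabs <- stage("falff", {
    if (config$mode == "volumetric") {
      vmap <- roi_voxel_map(template)
      cohort <- lapply(cohort, function(rec) {
        nd <- config$simulation$n_discard
        rec$data <- rec$data[(nd + 1):nrow(rec$data), , drop = FALSE]
        vol <- recording_to_volume(rec, vmap)
        fmap <- falff_volume(vol$data, rec$tr, mask = vol$mask,
                             bands = config$bands)
        filled <- ifelse(is.finite(fmap), fmap, 0)
        fmap <- ifelse(vol$mask, smooth_gaussian(filled, 6, vmap$voxel_size),
                       NA_real_)
        fmap <- normalize_global_mean(fmap, mask = is.finite(fmap) & vol$mask)
        rec$data <- matrix(roi_aggregate(fmap, template, vmap), nrow = 1,
                           dimnames = list(NULL, template$name))
        rec
      })
      lapply(c(EC = "EC", EO = "EO"), function(cond) {
        recs <- Filter(function(r) r$condition == cond, cohort)
        vals <- do.call(rbind, lapply(recs, `[[`, "data"))
        rownames(vals) <- vapply(recs, `[[`, character(1), "subject_id")
        structure(list(values = vals, condition = cond,
                       subject_ids = rownames(vals),
                       roi_names = template$name), class = "falff_table")
      })
    } else {
      lapply(c(EC = "EC", EO = "EO"), function(cond)
        falff_feature_table(cohort, cond, bands = config$bands,
                            n_discard = config$simulation$n_discard))
    }
  })
  for (cond in names(tabs)) {
    p <- file.path(config$output_dir, sprintf("falff_%s.tsv", cond))
    artifacts[[paste0("falff_", cond)]] <- p
    write_tsv(data.frame(subject_id = tabs[[cond]]$subject_ids,
                         tabs[[cond]]$values, check.names = FALSE), p, prov)
  }

  z <- stage("zscores", score_all_rois(tabs$EC, tabs$EO, template = template))
  zrep <- as.data.frame(z)
  for (nm in names(config$criteria))
    zrep[[paste0("selected_", nm)]] <- config$criteria[[nm]]$predicate(z$z)
  artifacts[["zscores"]] <- file.path(config$output_dir, "zscores.tsv")
  write_tsv(zrep, artifacts[["zscores"]], prov)

  results <- stage("decode", run_criterion_comparison(
    tabs$EC, tabs$EO, z, criteria = config$criteria,
    split_seed = config$split_seed, cost = config$svm_cost))
  runs <- attr(results, "runs")
  for (nm in names(config$criteria)) {
    pattern <- suppressWarnings(select_pattern(z, config$criteria[[nm]]))
    pp <- file.path(config$output_dir, sprintf("pattern_%s.tsv", nm))
    artifacts[[paste0("pattern_", nm)]] <- pp
    write_tsv(as.data.frame(pattern), pp, prov)
    if (!is.null(runs[[nm]])) {
      rp <- file.path(config$output_dir, sprintf("roc_%s.tsv", nm))
      artifacts[[paste0("roc_", nm)]] <- rp
      write_tsv(runs[[nm]][[1]]$roc, rp, prov)
    }
  }
  artifacts[["results"]] <- file.path(config$output_dir, "results.tsv")
  write_tsv(cbind(data.frame(split_seed = config$split_seed),
                  as.data.frame(results)), artifacts[["results"]], prov)
  say("decoding: %s",
      paste(sprintf("%s=%.0f%%", results$criterion, results$accuracy),
            collapse = ", "))
  say("done")
  list(config = config, template = template, zscores = z, results = results,
       artifacts = artifacts)
}

#' Validate the built-in reference pattern fixture
#'
#' Feeds the published 28-region Z values through pattern selection and
#' checks every derivable count: the four criterion pattern sizes
#' (28, 21, 13, 7), the sensorimotor share of the Z > 1.96 pattern (86%
#' after rounding), its full module composition (sensorimotor 18, default 1,
#' cingulo-opercular 2), and that the per-module counts of the |Z| > 1.96
#' pattern sum to 28.
#'
#' @param regions the fixture template (default [reference_regions()]);
#'   exposed so damaged fixtures can be shown to fail.
#' @param error_on_fail stop with a detailed diff on any mismatch
#'   (default TRUE).
#' @return data.frame of checks (`check`, `expected`, `observed`, `pass`),
#'   invisibly when all pass.
#' @export
validate_against_fixture <- function(regions = reference_regions(),
                                     error_on_fail = TRUE) {
  z <- zscores_from_template(regions)
  crit <- study_criteria()
  sizes <- vapply(crit, function(cr)
    nrow(suppressWarnings(select_pattern(z, cr))), integer(1))
  checks <- data.frame(
    check = c("n |Z|>1.96", "n Z>1.96", "n Z>2.25", "n Z<-1.96"),
    expected = c(28, 21, 13, 7),
    observed = as.numeric(sizes[c("abs_gt", "pos_gt", "pos_gt_strict",
                                  "neg_lt")]),
    stringsAsFactors = FALSE)
  pos <- suppressWarnings(select_pattern(z, crit$pos_gt))
  if (nrow(pos) > 0) {
    comp <- module_composition(pos)
    sm <- comp$percent[comp$module == "sensorimotor"]
    counts <- setNames(comp$n, comp$module)
    cnt <- function(nm) if (is.na(counts[nm])) 0 else counts[[nm]]
    checks <- rbind(checks, data.frame(
      check = c("sensorimotor % of Z>1.96 (rounded)",
                "sensorimotor n of Z>1.96", "default n of Z>1.96",
                "cingulo-opercular n of Z>1.96"),
      expected = c(86, 18, 1, 2),
      observed = c(round(if (length(sm)) sm else 0),
                   cnt("sensorimotor"), cnt("default"),
                   cnt("cingulo-opercular"))))
  }
  absp <- suppressWarnings(select_pattern(z, crit$abs_gt))
  checks <- rbind(checks, data.frame(
    check = "module counts of |Z|>1.96 sum",
    expected = 28,
    observed = if (nrow(absp)) sum(module_composition(absp)$n) else 0))
  checks$pass <- checks$expected == checks$observed
  rownames(checks) <- NULL
  if (error_on_fail && !all(checks$pass)) {
    bad <- checks[!checks$pass, , drop = FALSE]
    stop("fixture validation failed:\n",
         paste(sprintf("  %s: expected %g, observed %g", bad$check,
                       bad$expected, bad$observed), collapse = "\n"),
         call. = FALSE)
  }
  if (all(checks$pass)) invisible(checks) else checks
}
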
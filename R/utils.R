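# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package internals never
#' disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

# Deterministic stream of sub-seeds (kept < 2^31 so set.seed() accepts them).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Write a table as TSV with provenance comment lines
#'
#' Header lines start with `#` so the files stay `read_tsv()`-compatible and
#' byte-identical across reruns of the same configuration (no timestamps).
#' @keywords internal
#' @noRd
write_tsv <- function(df, path, provenance = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(provenance))
    writeLines(paste0("# ", provenance), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}
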
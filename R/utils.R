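# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores whatever RNG
#' state existed before the call. All stochastic functions in the package
#' route their randomness through this helper so that no call ever
#' perturbs the user's global RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# stop() with sprintf formatting and no call in the message
abort <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

warn <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}

# Write a data.frame as plain TSV (no quoting, no row names) -- the
# package's canonical tabular output format.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# JSON provenance sidecar written next to every CLI output.
write_provenance <- function(path, record) {
  record$package_version <- as.character(utils::packageVersion("clinekit"))
  record$r_version <- paste(R.version$major, R.version$minor, sep = ".")
  jsonlite::write_json(record, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
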
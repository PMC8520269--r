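# Parameters bgc's estpost extractor routinely emits. Unknown names are
# passed through with a warning because the emitted set depends on the
# model options used for the run.
KNOWN_BGC_PARAMS <- c("LnL", "alpha", "beta", "hi",
                      "gamma-quantile", "zeta-quantile")

# alpha and beta must have matching replicate sets: outlier detection
# consumes both jointly.
PAIRED_PARAMS <- c("alpha", "beta")

#' Discover bgc posterior replicate files
#'
#' Scans a directory for estpost-extracted bgc output files named
#' `<prefix>_stat_<param>_<replicate>` (the convention required of
#' independent bgc replicate runs) and groups them by parameter, ordered
#' by replicate number. Replicate numbers may be zero-padded.
#'
#' @param dir Directory to scan.
#' @param prefix Shared file-name prefix of the replicate set.
#' @return Named list: for each parameter, a character vector of file
#'   paths sorted by replicate integer.
#' @export
discover_replicates <- function(dir, prefix) {
  if (!dir.exists(dir)) abort("directory not found: %s", dir)
  files <- list.files(dir)
  lead <- paste0(prefix, "_stat_")
  rest <- substring(files[startsWith(files, lead)], nchar(lead) + 1L)
  fname <- files[startsWith(files, lead)]
  hits <- regmatches(rest, regexec("^(.+)_([0-9]+)$", rest))
  keep <- lengths(hits) == 3
  if (!any(keep)) {
    abort("no files matching '%s_stat_<param>_<replicate>' in %s",
          prefix, dir)
  }
  param <- vapply(hits[keep], `[`, character(1), 2)
  rep_no <- as.integer(vapply(hits[keep], `[`, character(1), 3))
  fname <- fname[keep]

  unknown <- setdiff(unique(param), KNOWN_BGC_PARAMS)
  if (length(unknown)) {
    warn("unknown bgc parameter name(s) passed through: %s",
         paste(unknown, collapse = ", "))
  }

  out <- lapply(split(seq_along(fname), param), function(idx) {
    file.path(dir, fname[idx][order(rep_no[idx])])
  })
  present <- intersect(PAIRED_PARAMS, names(out))
  if (length(present) == 2 && length(out$alpha) != length(out$beta)) {
    short <- if (length(out$alpha) < length(out$beta)) "alpha" else "beta"
    long <- setdiff(PAIRED_PARAMS, short)
    missing_reps <- setdiff(basename(out[[long]]),
                            sub(paste0("_", short, "_"), paste0("_", long, "_"),
                                basename(out[[short]]), fixed = TRUE))
    abort("alpha has %d replicate file(s) but beta has %d; missing: %s",
          length(out$alpha), length(out$beta),
          paste(sub(paste0("_", long, "_"), paste0("_", short, "_"),
                    missing_reps, fixed = TRUE), collapse = ", "))
  }
  out
}

#' Parse one estpost-extracted posterior file
#'
#' estpost writes comma-separated numeric text whose orientation depends
#' on the estpost version and flags used; rather than sniffing, the
#' orientation and header presence are declared explicitly so parsing is
#' deterministic. The result is always normalized to draws x entities
#' (entities are loci for cline parameters, admixed individuals for hybrid
#' index, a single column for the log-likelihood).
#'
#' @param path File path.
#' @param orientation `"samples_as_rows"` (each line one MCMC draw) or
#'   `"entities_as_rows"` (each line one locus/individual).
#' @param has_header Discard the first line before parsing.
#' @return Numeric matrix, draws in rows and entities in columns.
#' @export
parse_estpost_file <- function(path,
                               orientation = c("samples_as_rows",
                                               "entities_as_rows"),
                               has_header = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort("posterior file not found: %s", path)
  lines <- readLines(path)
  if (has_header) lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("no data rows in %s", path)
  rows <- strsplit(lines, ",", fixed = TRUE)
  n_col <- length(rows[[1]])
  width <- lengths(rows)
  if (any(width != n_col)) {
    abort("ragged row %d in %s: %d fields, expected %d",
          which(width != n_col)[1], path,
          width[width != n_col][1], n_col)
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) abort("non-numeric cell in %s", path)
  m <- matrix(vals, ncol = n_col, byrow = TRUE)
  if (orientation == "entities_as_rows") m <- t(m)
  m
}

#' Combine bgc posterior replicates with burn-in and thinning
#'
#' Parses each replicate file of each parameter, discards the first
#' `burnin` draws, retains every `thin`-th draw thereafter (0-based draw
#' indices `i >= burnin` with `(i - burnin) %% thin == 0`), and
#' concatenates replicates in replicate order. Per-replicate retained
#' counts follow `ceiling((S_r - burnin) / thin)` for a replicate of
#' `S_r` draws. Replicate provenance is recorded per retained draw so that
#' traces can be inspected for convergence before outlier detection.
#'
#' @param files Named list of per-parameter file vectors, as returned by
#'   [discover_replicates()], or a directory path plus `prefix`.
#' @param burnin Number of initial draws discarded from every replicate;
#'   must be smaller than the shortest replicate.
#' @param thin Keep every `thin`-th draw (>= 1).
#' @param prefix Required when `files` is a directory path.
#' @param orientation,has_header Passed to [parse_estpost_file()].
#' @return An object of class `bgc_posterior`: a list with `params` (per
#'   parameter: `samples` draws x entities matrix and `replicate` integer
#'   vector per retained draw), `burnin`, `thin`, and
#'   `replicate_lengths`.
#' @export
combine_bgc_output <- function(files, burnin = 0, thin = 1, prefix = NULL,
                               orientation = "samples_as_rows",
                               has_header = FALSE) {
  if (is.character(files) && length(files) == 1 && dir.exists(files)) {
    if (is.null(prefix)) abort("prefix is required when `files` is a directory")
    files <- discover_replicates(files, prefix)
  }
  if (!is.list(files) || is.null(names(files))) {
    abort("`files` must be a named per-parameter list of file paths")
  }
  if (thin < 1) abort("thin must be >= 1")
  if (burnin < 0) abort("burnin must be >= 0")

  params <- lapply(names(files), function(p) {
    mats <- lapply(files[[p]], parse_estpost_file,
                   orientation = orientation, has_header = has_header)
    n_ent <- unique(vapply(mats, ncol, integer(1)))
    if (length(n_ent) != 1) {
      abort("replicates of '%s' disagree on entity count: %s",
            p, paste(vapply(mats, ncol, integer(1)), collapse = ", "))
    }
    kept <- lapply(seq_along(mats), function(r) {
      S <- nrow(mats[[r]])
      if (burnin >= S) {
        abort("burnin (%d) >= draw count (%d) in replicate %d of '%s' (%s)",
              burnin, S, r, p, files[[p]][r])
      }
      idx <- seq.int(burnin + 1L, S, by = thin)
      list(samples = mats[[r]][idx, , drop = FALSE],
           replicate = rep.int(r, length(idx)))
    })
    list(
      samples = do.call(rbind, lapply(kept, `[[`, "samples")),
      replicate = unlist(lapply(kept, `[[`, "replicate")),
      replicate_lengths = vapply(mats, nrow, integer(1))
    )
  })
  names(params) <- names(files)

  structure(
    list(params = params, burnin = as.integer(burnin),
         thin = as.integer(thin),
         replicate_lengths = lapply(params, `[[`, "replicate_lengths")),
    class = "bgc_posterior"
  )
}

#' @export
print.bgc_posterior <- function(x, ...) {
  cat(sprintf("bgc_posterior (burnin=%d, thin=%d)\n", x$burnin, x$thin))
  for (p in names(x$params)) {
    s <- x$params[[p]]
    cat(sprintf("  %-16s %6d retained draws x %5d entities (%d replicates)\n",
                p, nrow(s$samples), ncol(s$samples),
                length(unique(s$replicate))))
  }
  invisible(x)
}

#' Per-replicate trace series and mixing summaries
#'
#' Prepares plot-ready trace data (retained draw index vs value, grouped
#' by replicate) for one parameter, together with per-replicate summary
#' statistics used to judge mixing: mean, variance, and lag-1
#' autocorrelation (defined as 0 for a constant trace). Diagnostics are
#' advisory; nothing downstream is gated on them.
#'
#' @param ps A `bgc_posterior` from [combine_bgc_output()].
#' @param param Parameter to trace (default `"LnL"`).
#' @param entity Entity (locus/individual) column to trace; `NULL` traces
#'   the per-draw mean over all entities.
#' @return A list with `trace` (data frame: `draw`, `value`, `replicate`)
#'   and `summary` (data frame per replicate: `mean`, `variance`,
#'   `lag1_autocorr`, `n`).
#' @export
trace_stats <- function(ps, param = "LnL", entity = NULL) {
  stopifnot(inherits(ps, "bgc_posterior"))
  if (!param %in% names(ps$params)) {
    abort("parameter '%s' not present; have: %s", param,
          paste(names(ps$params), collapse = ", "))
  }
  s <- ps$params[[param]]
  series <- if (is.null(entity)) {
    rowMeans(s$samples)
  } else {
    if (entity < 1 || entity > ncol(s$samples)) {
      abort("entity %d out of range (1..%d)", entity, ncol(s$samples))
    }
    s$samples[, entity]
  }
  trace <- data.frame(draw = stats::ave(seq_along(series), s$replicate,
                                        FUN = seq_along),
                      value = series, replicate = s$replicate)
  lag1 <- function(x) {
    if (length(x) < 2 || stats::var(x) == 0) return(0)
    stats::cor(x[-length(x)], x[-1])
  }
  summary <- do.call(rbind, lapply(split(series, s$replicate), function(x) {
    data.frame(mean = mean(x),
               variance = if (length(x) > 1) stats::var(x) else 0,
               lag1_autocorr = lag1(x), n = length(x))
  }))
  summary <- cbind(replicate = as.integer(rownames(summary)), summary)
  rownames(summary) <- NULL
  list(trace = trace, summary = summary)
}

#' Write a combined posterior as a tabular archive
#'
#' One TSV per parameter (columns: replicate, then one column per entity)
#' plus a JSON provenance sidecar recording burn-in, thinning, and
#' per-replicate draw counts.
#'
#' @param ps A `bgc_posterior`.
#' @param outdir Output directory.
#' @param prefix File-name prefix.
#' @return Named vector of written paths, invisibly.
#' @export
write_posterior <- function(ps, outdir, prefix = "posterior") {
  stopifnot(inherits(ps, "bgc_posterior"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (p in names(ps$params)) {
    s <- ps$params[[p]]
    df <- data.frame(replicate = s$replicate, s$samples)
    names(df) <- c("replicate", paste0("entity_", seq_len(ncol(s$samples))))
    path <- file.path(outdir, paste0(prefix, "_", p, ".tsv"))
    write_tsv(df, path)
    paths[p] <- path
  }
  side <- file.path(outdir, paste0(prefix, "_provenance.json"))
  write_provenance(side, list(
    burnin = ps$burnin, thin = ps$thin,
    replicate_lengths = ps$replicate_lengths
  ))
  paths["provenance"] <- side
  invisible(paths)
}

#' Read a posterior archive written by [write_posterior()]
#'
#' @param outdir Directory holding the archive.
#' @param prefix File-name prefix used when writing.
#' @return A `bgc_posterior`.
#' @export
read_posterior <- function(outdir, prefix = "posterior") {
  side <- file.path(outdir, paste0(prefix, "_provenance.json"))
  if (!file.exists(side)) abort("no provenance sidecar at %s", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  tsvs <- list.files(outdir, pattern = paste0("^", prefix, "_.*\\.tsv$"),
                     full.names = TRUE)
  params <- list()
  for (path in tsvs) {
    p <- sub(paste0("^", prefix, "_(.*)\\.tsv$"), "\\1", basename(path))
    df <- read_tsv(path)
    params[[p]] <- list(
      samples = as.matrix(df[, -1, drop = FALSE]),
      replicate = as.integer(df$replicate),
      replicate_lengths = unlist(meta$replicate_lengths[[p]])
    )
    dimnames(params[[p]]$samples) <- NULL
  }
  structure(
    list(params = params, burnin = as.integer(meta$burnin),
         thin = as.integer(meta$thin),
         replicate_lengths = lapply(params, `[[`, "replicate_lengths")),
    class = "bgc_posterior"
  )
}
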
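# The bgc input dialect written and read here:
#   parental files: per locus a header line "locus_<i>", then one line per
#     parental individual with two whitespace-separated integers (genotype
#     mode: copies of allele 1 and allele 2, summing to 2; read-count
#     mode: read depths for the two alleles);
#   admixed file: per locus "locus_<i>", then per admixed population a
#     "pop_<j>" header, then individual lines as above;
#   missing data: "-9 -9";
#   locus order identical across all three files.

#' Write bgc input files
#'
#' Exports a genotype matrix to the three-file input format consumed by
#' the Bayesian genomic cline program bgc: one file per parental
#' population and one for the admixed population(s). In genotype mode each
#' individual line holds the two allele copy counts (summing to 2); in
#' read-count mode it holds the read depths supporting each allele, which
#' lets bgc model genotype uncertainty. Missing data is `-9 -9`.
#'
#' @param gm A [genotype_matrix()] with at least one sample in each
#'   parental population and one admixed sample.
#' @param outdir Output directory (created if needed).
#' @param mode `"genotype"` or `"readcount"`.
#' @param rc A [read_count_matrix()]; required in read-count mode.
#' @param p0,p1 Population labels of the two parental populations.
#' @param prefix File-name prefix.
#' @return Named character vector of the three file paths
#'   (`parental0`, `parental1`, `admixed`), invisibly.
#' @export
write_bgc_input <- function(gm, outdir, mode = c("genotype", "readcount"),
                            rc = NULL, p0 = "P0", p1 = "P1",
                            prefix = "bgc") {
  mode <- match.arg(mode)
  roles <- assign_roles(gm, p0 = p0, p1 = p1)
  if (mode == "readcount") {
    if (is.null(rc)) abort("read-count mode requires a read_count_matrix")
    if (!identical(rc$sample_ids, gm$sample_ids) ||
        !identical(rc$locus_ids, gm$locus_ids)) {
      abort("read_count_matrix samples/loci do not match the genotype matrix")
    }
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  line_for <- function(i, j) {
    if (mode == "genotype") {
      g <- gm$genotypes[i, j]
      if (is.na(g)) "-9 -9" else paste(2L - g, g)
    } else {
      c1 <- rc$counts1[i, j]; c2 <- rc$counts2[i, j]
      if (is.na(c1) || is.na(c2)) "-9 -9" else paste(c1, c2)
    }
  }

  n_loci <- length(gm$locus_ids)
  parental_lines <- function(rows) {
    out <- character(0)
    for (j in seq_len(n_loci)) {
      out <- c(out, paste0("locus_", j),
               vapply(rows, line_for, character(1), j = j))
    }
    out
  }
  admixed_lines <- function() {
    adm_rows_by_pop <- lapply(roles$admixed_pops, function(p) {
      which(gm$pop_labels == p & roles$role == "ADMIXED")
    })
    out <- character(0)
    for (j in seq_len(n_loci)) {
      out <- c(out, paste0("locus_", j))
      for (k in seq_along(adm_rows_by_pop)) {
        out <- c(out, paste0("pop_", k),
                 vapply(adm_rows_by_pop[[k]], line_for, character(1), j = j))
      }
    }
    out
  }

  paths <- c(
    parental0 = file.path(outdir, paste0(prefix, "_p0.txt")),
    parental1 = file.path(outdir, paste0(prefix, "_p1.txt")),
    admixed = file.path(outdir, paste0(prefix, "_admixed.txt"))
  )
  writeLines(parental_lines(which(roles$role == "P0")), paths["parental0"])
  writeLines(parental_lines(which(roles$role == "P1")), paths["parental1"])
  writeLines(admixed_lines(), paths["admixed"])
  invisible(paths)
}

#' Read bgc input files back into a genotype matrix
#'
#' Inverse of [write_bgc_input()] (genotype mode) up to sample names,
#' which are synthesized positionally. Used to verify exports round-trip
#' exactly, and to inspect third-party bgc inputs that follow the same
#' dialect.
#'
#' @param parental0,parental1,admixed Paths to the three bgc input files.
#' @param strict Reject any line that is not a recognised header or a
#'   two-integer data line (default `TRUE`).
#' @return A [genotype_matrix()] with population labels `P0`, `P1`, and
#'   `ADMIXED_<j>`.
#' @export
read_bgc_input <- function(parental0, parental1, admixed, strict = TRUE) {
  parse_two_int <- function(line, where) {
    xs <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(xs) != 2) {
      abort("malformed data line in %s: '%s'", where, line)
    }
    v <- suppressWarnings(as.integer(xs))
    if (anyNA(v)) abort("non-integer data line in %s: '%s'", where, line)
    v
  }
  geno_from <- function(v, where) {
    if (all(v == -9L)) return(NA_integer_)
    if (any(v < 0) || sum(v) != 2L) {
      if (strict) abort("line in %s does not sum to 2 copies: '%s %s'",
                        where, v[1], v[2])
      return(NA_integer_)
    }
    v[2]
  }

  parse_parental <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    locus_starts <- grep("^locus_", lines)
    if (!length(locus_starts)) abort("no locus headers in %s", path)
    per_locus <- diff(c(locus_starts, length(lines) + 1L)) - 1L
    if (length(unique(per_locus)) != 1) {
      abort("unequal individual counts across loci in %s", path)
    }
    n_ind <- per_locus[1]
    g <- matrix(NA_integer_, nrow = n_ind, ncol = length(locus_starts))
    for (j in seq_along(locus_starts)) {
      for (i in seq_len(n_ind)) {
        v <- parse_two_int(lines[locus_starts[j] + i], path)
        g[i, j] <- geno_from(v, path)
      }
    }
    g
  }

  parse_admixed <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    locus_starts <- grep("^locus_", lines)
    if (!length(locus_starts)) abort("no locus headers in %s", path)
    blocks <- Map(function(a, b) if (a > b) character(0) else lines[a:b],
                  locus_starts + 1L,
                  c(locus_starts[-1] - 1L, length(lines)))
    if (any(lengths(blocks) == 0L)) abort("empty admixed locus block in %s",
                                          path)
    parse_block <- function(block) {
      pop_starts <- grep("^pop_", block)
      if (!length(pop_starts) || pop_starts[1] != 1L) {
        abort("admixed locus block in %s does not start with a pop header",
              path)
      }
      pops <- Map(function(a, b) block[a:b], pop_starts + 1L,
                  c(pop_starts[-1] - 1L, length(block)))
      if (any(lengths(pops) == 0L)) abort("empty pop section in %s", path)
      lapply(pops, function(ls) {
        vapply(ls, function(l) geno_from(parse_two_int(l, path), path),
               integer(1), USE.NAMES = FALSE)
      })
    }
    per_locus <- lapply(blocks, parse_block)
    shape <- lengths(per_locus[[1]])
    sizes <- vapply(per_locus[[1]], length, integer(1))
    for (b in per_locus) {
      if (length(b) != length(shape) ||
          !identical(vapply(b, length, integer(1)), sizes)) {
        abort("inconsistent admixed population structure across loci in %s",
              path)
      }
    }
    g <- do.call(cbind, lapply(per_locus, function(b) unlist(b)))
    list(genotypes = g, pop_sizes = sizes)
  }

  g0 <- parse_parental(parental0)
  g1 <- parse_parental(parental1)
  adm <- parse_admixed(admixed)
  n_loci <- ncol(g0)
  if (ncol(g1) != n_loci || ncol(adm$genotypes) != n_loci) {
    abort("locus counts disagree across files: %d / %d / %d",
          n_loci, ncol(g1), ncol(adm$genotypes))
  }

  pops <- c(rep("P0", nrow(g0)), rep("P1", nrow(g1)),
            rep(paste0("ADMIXED_", seq_along(adm$pop_sizes)),
                times = adm$pop_sizes))
  geno <- rbind(g0, g1, adm$genotypes)
  genotype_matrix(
    genotypes = geno,
    sample_ids = sprintf("ind_%d", seq_len(nrow(geno))),
    pop_labels = pops,
    locus_ids = paste0("locus_", seq_len(n_loci))
  )
}
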
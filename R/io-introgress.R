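#' Write Introgress input files
#'
#' Exports a genotype matrix to the four tables consumed by the Introgress
#' likelihood cline program: admixed genotypes, the two parental genotype
#' tables, and a loci table. Genotypes are written as slash-separated
#' allele pairs (e.g. `A/C`), with missing data as `NA/NA`. Orientation is
#' fixed: loci as rows, individuals as columns; the first header row of
#' each genotype table carries the individuals' population labels and the
#' second their sample IDs. The loci table lists each locus id with type
#' code `C` (codominant).
#'
#' @inheritParams write_bgc_input
#' @return Named character vector of four paths (`admix`, `parental1`,
#'   `parental2`, `loci`), invisibly.
#' @export
write_introgress_input <- function(gm, outdir, p0 = "P0", p1 = "P1",
                                   prefix = "introgress") {
  roles <- assign_roles(gm, p0 = p0, p1 = p1)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  cell <- function(i, j) {
    g <- gm$genotypes[i, j]
    a <- gm$alleles[j, ]
    if (is.na(g) || anyNA(a)) return("NA/NA")
    paste(c(rep(a[1], 2L - g), rep(a[2], g)), collapse = "/")
  }
  table_for <- function(rows, path) {
    n_loci <- length(gm$locus_ids)
    body <- vapply(seq_len(n_loci), function(j) {
      paste(vapply(rows, cell, character(1), j = j), collapse = ",")
    }, character(1))
    header <- c(paste(gm$pop_labels[rows], collapse = ","),
                paste(gm$sample_ids[rows], collapse = ","))
    writeLines(c(header, body), path)
    path
  }

  paths <- c(
    admix = file.path(outdir, paste0(prefix, "_admix.csv")),
    parental1 = file.path(outdir, paste0(prefix, "_p1.csv")),
    parental2 = file.path(outdir, paste0(prefix, "_p2.csv")),
    loci = file.path(outdir, paste0(prefix, "_loci.csv"))
  )
  table_for(which(roles$role == "ADMIXED"), paths["admix"])
  table_for(which(roles$role == "P0"), paths["parental1"])
  table_for(which(roles$role == "P1"), paths["parental2"])
  loci_df <- data.frame(locus = gm$locus_ids, type = "C",
                        stringsAsFactors = FALSE)
  utils::write.csv(loci_df, paths["loci"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
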
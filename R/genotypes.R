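#' Genotype matrix container
#'
#' The central data structure for the input-preparation workflow: a
#' samples-by-loci matrix of diploid genotypes coded as the count of the
#' second (usually alternate) allele, i.e. 0, 1, 2, or `NA` for missing
#' calls. Each sample carries a population label; parental and admixed
#' roles are assigned from those labels at export time (see
#' [write_bgc_input()]).
#'
#' @param genotypes Integer matrix, samples in rows and loci in columns;
#'   entries must be 0, 1, 2, or `NA`.
#' @param sample_ids Character vector of unique sample names (row order).
#' @param pop_labels Character vector of population labels, one per sample.
#' @param locus_ids Character vector of unique locus names (column order).
#' @param alleles Character matrix with one row per locus and two columns
#'   (first and second allele symbol). The genotype value counts copies of
#'   the *second* allele.
#' @param allele_count Integer vector: number of distinct alleles observed
#'   at each locus (>= 1). Loci with more than two observed alleles cannot
#'   be represented as 0/1/2 and carry `NA` genotypes; the count is kept so
#'   that [filter_genotypes()] can drop them.
#' @param chrom,pos Optional per-locus physical coordinates (scaffold or
#'   chromosome name, 1-based bp) carried through from a VCF.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, sample_ids, pop_labels, locus_ids,
                            alleles = NULL, allele_count = NULL,
                            chrom = NULL, pos = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  if (length(sample_ids) != n) {
    abort("length(sample_ids) [%d] != number of genotype rows [%d]",
          length(sample_ids), n)
  }
  if (length(pop_labels) != n) {
    abort("length(pop_labels) [%d] != number of samples [%d]",
          length(pop_labels), n)
  }
  if (length(locus_ids) != m) {
    abort("length(locus_ids) [%d] != number of genotype columns [%d]",
          length(locus_ids), m)
  }
  if (anyDuplicated(sample_ids)) abort("sample_ids must be unique")
  if (anyDuplicated(locus_ids)) abort("locus_ids must be unique")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% 0:2)) {
    abort("genotype values must be 0, 1, 2, or NA")
  }
  if (is.null(alleles)) {
    alleles <- matrix(NA_character_, nrow = m, ncol = 2)
  } else {
    alleles <- matrix(as.character(alleles), nrow = m, ncol = 2)
  }
  if (is.null(allele_count)) {
    allele_count <- vapply(seq_len(m), function(j) {
      g <- genotypes[, j]
      g <- g[!is.na(g)]
      if (!length(g)) return(0L)
      length(unique(c(if (any(g < 2)) 1L, if (any(g > 0)) 2L)))
    }, integer(1))
  }
  structure(
    list(
      genotypes = genotypes,
      sample_ids = as.character(sample_ids),
      pop_labels = as.character(pop_labels),
      locus_ids = as.character(locus_ids),
      alleles = alleles,
      allele_count = as.integer(allele_count),
      chrom = if (is.null(chrom)) NULL else as.character(chrom),
      pos = if (is.null(pos)) NULL else as.integer(pos)
    ),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  tab <- table(x$pop_labels)
  cat("populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

# Subset a genotype_matrix by sample and/or locus index, keeping all
# per-sample and per-locus metadata aligned.
subset_gm <- function(gm, samples = NULL, loci = NULL) {
  if (is.null(samples)) samples <- seq_along(gm$sample_ids)
  if (is.null(loci)) loci <- seq_along(gm$locus_ids)
  genotype_matrix(
    genotypes = gm$genotypes[samples, loci, drop = FALSE],
    sample_ids = gm$sample_ids[samples],
    pop_labels = gm$pop_labels[samples],
    locus_ids = gm$locus_ids[loci],
    alleles = gm$alleles[loci, , drop = FALSE],
    allele_count = gm$allele_count[loci],
    chrom = gm$chrom[loci],
    pos = gm$pos[loci]
  )
}

#' Read count container
#'
#' Per-sample, per-locus read depths supporting each of a locus's two
#' alleles, as extracted from VCF allele-depth (AD) annotations. Used by
#' [write_bgc_input()] in read-count mode. Missing observations are `NA`
#' in both matrices; an explicit (0, 0) is preserved as written by the
#' variant caller.
#'
#' @param counts1,counts2 Integer matrices (samples x loci) of read counts
#'   supporting the first and second allele.
#' @param sample_ids,locus_ids Dimension names, as in [genotype_matrix()].
#' @return An object of class `read_count_matrix`.
#' @export
read_count_matrix <- function(counts1, counts2, sample_ids, locus_ids) {
  counts1 <- as.matrix(counts1); storage.mode(counts1) <- "integer"
  counts2 <- as.matrix(counts2); storage.mode(counts2) <- "integer"
  if (!identical(dim(counts1), dim(counts2))) {
    abort("allele-1 and allele-2 count matrices differ in dimension")
  }
  if (any(counts1 < 0, na.rm = TRUE) || any(counts2 < 0, na.rm = TRUE)) {
    abort("read counts must be non-negative")
  }
  if (length(sample_ids) != nrow(counts1) ||
      length(locus_ids) != ncol(counts1)) {
    abort("sample_ids/locus_ids do not match count matrix dimensions")
  }
  structure(
    list(counts1 = counts1, counts2 = counts2,
         sample_ids = as.character(sample_ids),
         locus_ids = as.character(locus_ids)),
    class = "read_count_matrix"
  )
}

#' Assign parental and admixed roles from population labels
#'
#' Maps each sample's population label to one of the roles required by the
#' bgc/Introgress exporters: parental population 0, parental population 1,
#' or admixed. Any label not named as parental is treated as an admixed
#' population.
#'
#' @param gm A [genotype_matrix()].
#' @param p0,p1 Population label(s) for the two parental populations.
#' @return A list with `role` (character vector per sample: "P0", "P1" or
#'   "ADMIXED") and `admixed_pops` (ordered unique admixed labels).
#' @export
assign_roles <- function(gm, p0 = "P0", p1 = "P1") {
  labs <- gm$pop_labels
  missing_p0 <- !any(labs %in% p0)
  missing_p1 <- !any(labs %in% p1)
  if (missing_p0) abort("no samples labelled as parental population 0 (%s)",
                        paste(p0, collapse = ","))
  if (missing_p1) abort("no samples labelled as parental population 1 (%s)",
                        paste(p1, collapse = ","))
  role <- ifelse(labs %in% p0, "P0", ifelse(labs %in% p1, "P1", "ADMIXED"))
  if (!any(role == "ADMIXED")) {
    abort("no admixed samples: every sample is labelled parental")
  }
  admixed_pops <- unique(labs[role == "ADMIXED"])
  list(role = role, admixed_pops = admixed_pops)
}

#' Read a population map
#'
#' A popmap is a two-column whitespace-separated text table mapping sample
#' names to population labels, the convention used by RADseq assembly
#' pipelines.
#'
#' @param path Path to the popmap file.
#' @return Named character vector: population label per sample name.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) abort("popmap not found: %s", path)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("sample", "pop"))
  if (anyDuplicated(df$sample)) {
    abort("duplicate sample in popmap: %s",
          df$sample[duplicated(df$sample)][1])
  }
  stats::setNames(as.character(df$pop), df$sample)
}

# Match popmap labels to a vector of sample names; hard error naming any
# sample absent from the popmap.
popmap_labels <- function(samples, popmap) {
  missing <- setdiff(samples, names(popmap))
  if (length(missing)) {
    abort("sample(s) missing from popmap: %s",
          paste(missing, collapse = ", "))
  }
  unname(popmap[samples])
}
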
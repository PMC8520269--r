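#' Read a VCF into a genotype matrix (and read counts when present)
#'
#' Parses a VCF (v4.x) with vcfR, joins population labels from a popmap,
#' and codes each diploid genotype as the count of the first ALT allele
#' (0/1/2, `NA` for missing). When per-genotype allele-depth (`AD`)
#' annotations are present, a [read_count_matrix()] of (REF, ALT) read
#' depths is returned alongside; otherwise the `read_counts` element is
#' `NULL`. Physical position (CHROM, POS) is retained as locus metadata
#' for downstream coordinate lifting.
#'
#' Genotype calls involving allele indices above 1 (second or later ALT
#' alleles) cannot be represented on a biallelic 0/1/2 scale and are set
#' missing; the locus's observed-allele count still reflects them so that
#' [filter_genotypes()] can drop non-biallelic sites.
#'
#' @param path Path to a VCF file (plain text or bgzip).
#' @param popmap Path to a two-column popmap file; every VCF sample must
#'   appear in it.
#' @return A list with elements `genotypes` ([genotype_matrix()]) and
#'   `read_counts` ([read_count_matrix()] or `NULL`).
#' @export
read_vcf <- function(path, popmap) {
  if (!file.exists(path)) abort("VCF not found: %s", path)
  pm <- read_popmap(popmap)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort("failed to parse VCF %s: %s",
                              path, conditionMessage(e))
  )
  fix <- vcf@fix
  n_loci <- nrow(fix)
  if (is.null(n_loci) || n_loci == 0L) abort("VCF contains no variant records")

  gt <- vcfR::extract.gt(vcf, element = "GT")  # loci x samples
  samples <- colnames(gt)
  pops <- popmap_labels(samples, pm)

  ids <- fix[, "ID"]
  ids <- ifelse(is.na(ids) | ids == ".",
                paste(fix[, "CHROM"], fix[, "POS"], sep = "_"), ids)
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids, sep = "_")
  }

  alt1 <- vapply(strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",",
                          fixed = TRUE),
                 function(a) if (length(a)) a[1] else NA_character_,
                 character(1))
  alleles <- cbind(fix[, "REF"], alt1)

  parsed <- parse_gt_matrix(gt)
  geno <- t(parsed$dose)           # samples x loci
  allele_count <- parsed$allele_count

  gm <- genotype_matrix(
    genotypes = geno,
    sample_ids = samples,
    pop_labels = pops,
    locus_ids = ids,
    alleles = alleles,
    allele_count = allele_count,
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"])
  )

  rc <- NULL
  fmt <- vcf@gt[, "FORMAT"]
  if (any(vapply(strsplit(fmt, ":", fixed = TRUE),
                 function(f) "AD" %in% f, logical(1)))) {
    ad <- vcfR::extract.gt(vcf, element = "AD")
    if (!all(is.na(ad))) {
      split_ad <- function(k) {
        v <- suppressWarnings(
          vapply(strsplit(ifelse(is.na(ad), ",", ad), ",", fixed = TRUE),
                 function(x) as.integer(x[k]), integer(1)))
        t(matrix(v, nrow = nrow(ad)))  # samples x loci
      }
      rc <- read_count_matrix(split_ad(1), split_ad(2),
                              sample_ids = samples, locus_ids = ids)
    }
  }
  list(genotypes = gm, read_counts = rc)
}

# Parse a vcfR GT matrix (loci x samples) into ALT-allele dosage and the
# per-locus count of distinct observed alleles.
parse_gt_matrix <- function(gt) {
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  allele_count <- integer(nrow(gt))
  for (i in seq_len(nrow(gt))) {
    seen <- integer(0)
    for (j in seq_len(ncol(gt))) {
      g <- gt[i, j]
      if (is.na(g) || g %in% c(".", "./.", ".|.")) next
      al <- strsplit(g, "[/|]")[[1]]
      if (any(al == ".")) next
      ai <- suppressWarnings(as.integer(al))
      if (anyNA(ai)) next
      seen <- union(seen, ai)
      if (all(ai <= 1L) && length(ai) == 2L) {
        dose[i, j] <- sum(ai)
      }
    }
    allele_count[i] <- length(seen)
  }
  # a site where nothing was called still counts its declared alleles as 0
  list(dose = dose, allele_count = pmax(allele_count, 0L))
}
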
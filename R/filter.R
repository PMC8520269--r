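#' Construct a genotype filtering specification
#'
#' Bundles the SNP-matrix filtering rules applied before export to the
#' cline programs: occupancy per locus and per individual, minor allele
#' frequency, removal of non-biallelic and monomorphic sites, and random
#' locus subsampling.
#'
#' @param max_missing_per_locus Maximum tolerated missing-call fraction per
#'   locus, in \[0, 1\] (1 disables the rule).
#' @param max_missing_per_individual Maximum tolerated missing-call
#'   fraction per individual, in \[0, 1\].
#' @param min_maf Minimum minor allele frequency, in \[0, 0.5\] (0 disables).
#' @param biallelic_only Drop loci with more than two observed alleles.
#' @param drop_monomorphic Drop loci where only one allele is observed
#'   among non-missing genotypes.
#' @param subsample_n Optional number of loci to retain by random
#'   subsampling (applied last).
#' @param seed Seed for the subsampling draw; required when `subsample_n`
#'   is set so that runs are reproducible.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(max_missing_per_locus = 1,
                        max_missing_per_individual = 1,
                        min_maf = 0,
                        biallelic_only = TRUE,
                        drop_monomorphic = TRUE,
                        subsample_n = NULL,
                        seed = NULL) {
  chk_frac <- function(x, nm, hi = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > hi) {
      abort("%s must be a single number in [0, %s]", nm, hi)
    }
  }
  chk_frac(max_missing_per_locus, "max_missing_per_locus")
  chk_frac(max_missing_per_individual, "max_missing_per_individual")
  chk_frac(min_maf, "min_maf", hi = 0.5)
  if (!is.null(subsample_n)) {
    if (subsample_n < 1) abort("subsample_n must be a positive integer")
    if (is.null(seed)) abort("subsample_n requires an explicit seed")
  }
  structure(
    list(max_missing_per_locus = max_missing_per_locus,
         max_missing_per_individual = max_missing_per_individual,
         min_maf = min_maf,
         biallelic_only = isTRUE(biallelic_only),
         drop_monomorphic = isTRUE(drop_monomorphic),
         subsample_n = subsample_n,
         seed = seed),
    class = "filter_spec"
  )
}

#' Filter a genotype matrix
#'
#' Applies the rules in a [filter_spec()] in a fixed, documented order:
#' \enumerate{
#'   \item drop non-biallelic loci (`biallelic_only`),
#'   \item drop monomorphic loci, judged from the per-locus allele count
#'     recorded at read time (`drop_monomorphic`),
#'   \item drop loci whose missing fraction exceeds
#'     `max_missing_per_locus`,
#'   \item drop individuals whose missing fraction over the *surviving*
#'     loci exceeds `max_missing_per_individual`,
#'   \item drop loci whose minor allele frequency (over non-missing calls
#'     of surviving individuals) is below `min_maf`,
#'   \item randomly subsample `subsample_n` loci with the spec's seed.
#' }
#' The order matters because each stage's statistics are computed on the
#' previous stage's survivors; it is fixed so that identical inputs and
#' spec always yield byte-identical outputs.
#'
#' @param gm A [genotype_matrix()].
#' @param spec A [filter_spec()].
#' @return A list with `genotypes` (the filtered [genotype_matrix()]) and
#'   `report` (a `filter_report` data frame of per-stage removal counts).
#' @export
filter_genotypes <- function(gm, spec) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(spec, "filter_spec"))
  stages <- c("non_biallelic", "monomorphic", "locus_missing",
              "individual_missing", "maf", "subsample")
  removed <- stats::setNames(integer(length(stages)), stages)

  fatal <- function(stage) {
    abort("filtering removed everything at stage '%s'", stage)
  }

  # 1. non-biallelic
  if (spec$biallelic_only) {
    keep <- gm$allele_count <= 2
    removed["non_biallelic"] <- sum(!keep)
    if (!any(keep)) fatal("non_biallelic")
    gm <- subset_gm(gm, loci = which(keep))
  }

  # 2. monomorphic: fewer than two alleles in the per-locus allele count
  # recorded at read time (VCF declarations or bases observed in the
  # alignment), so a polymorphic locus is not re-judged after missing
  # calls hide one allele
  if (spec$drop_monomorphic) {
    keep <- gm$allele_count >= 2L
    removed["monomorphic"] <- sum(!keep)
    if (!any(keep)) fatal("monomorphic")
    gm <- subset_gm(gm, loci = which(keep))
  }

  # 3. per-locus occupancy
  if (spec$max_missing_per_locus < 1) {
    miss <- colMeans(is.na(gm$genotypes))
    keep <- miss <= spec$max_missing_per_locus
    removed["locus_missing"] <- sum(!keep)
    if (!any(keep)) fatal("locus_missing")
    gm <- subset_gm(gm, loci = which(keep))
  }

  # 4. per-individual occupancy, over surviving loci
  if (spec$max_missing_per_individual < 1) {
    miss <- rowMeans(is.na(gm$genotypes))
    keep <- miss <= spec$max_missing_per_individual
    removed["individual_missing"] <- sum(!keep)
    if (!any(keep)) fatal("individual_missing")
    gm <- subset_gm(gm, samples = which(keep))
  }

  # 5. minor allele frequency over retained individuals' non-missing calls
  if (spec$min_maf > 0) {
    maf <- vapply(seq_along(gm$locus_ids), function(j) {
      g <- gm$genotypes[, j]
      g <- g[!is.na(g)]
      if (!length(g)) return(0)
      p <- sum(g) / (2 * length(g))
      min(p, 1 - p)
    }, numeric(1))
    keep <- maf >= spec$min_maf
    removed["maf"] <- sum(!keep)
    if (!any(keep)) fatal("maf")
    gm <- subset_gm(gm, loci = which(keep))
  }

  # 6. random subsample, isolated PRNG stream
  if (!is.null(spec$subsample_n) &&
      spec$subsample_n < length(gm$locus_ids)) {
    pick <- with_seed(spec$seed,
                      sort(sample.int(length(gm$locus_ids),
                                      spec$subsample_n)))
    removed["subsample"] <- length(gm$locus_ids) - length(pick)
    gm <- subset_gm(gm, loci = pick)
  }

  report <- data.frame(stage = stages, removed = as.integer(removed),
                       stringsAsFactors = FALSE)
  class(report) <- c("filter_report", class(report))
  list(genotypes = gm, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report (items removed per stage):\n")
  print.data.frame(x)
  invisible(x)
}

#' Write a filter report as TSV
#'
#' @param report A `filter_report` from [filter_genotypes()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_filter_report <- function(report, path) {
  write_tsv(as.data.frame(report), path)
}
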
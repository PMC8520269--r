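# Shared fixture builders. Everything is generated in code at test time;
# no data files ship with the tests.

# The 5-locus toy matrix whose filtering outcome is enumerable by hand:
#   L1 [0,1,2,1]  biallelic, polymorphic, complete, MAF 0.5  -> survives
#   L2 [NA,NA,0,0] 50% missing                               -> occupancy
#   L3 [0,0,0,0]  monomorphic                                -> monomorphic
#   L4 [0,0,0,1]  MAF 1/8 = 0.125 < 0.15                     -> MAF
#   L5 triallelic                                            -> biallelic
toy_filter_matrix <- function() {
  geno <- cbind(
    c(0L, 1L, 2L, 1L),
    c(NA, NA, 0L, 0L),
    c(0L, 0L, 0L, 0L),
    c(0L, 0L, 0L, 1L),
    c(NA, NA, NA, NA)
  )
  genotype_matrix(
    geno,
    sample_ids = paste0("s", 1:4),
    pop_labels = c("P0", "P0", "P1", "ADMIXED"),
    locus_ids = paste0("L", 1:5),
    alleles = cbind(rep("A", 5), rep("C", 5)),
    allele_count = c(2L, 2L, 1L, 2L, 3L)
  )
}

# Write estpost-dialect files from given draw matrices (draws x loci).
write_estpost_fixture <- function(dir, prefix, param, mats) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_along(mats)) {
    path <- file.path(dir, sprintf("%s_stat_%s_%d", prefix, param, r))
    writeLines(apply(mats[[r]], 1, paste, collapse = ","), path)
  }
  invisible(dir)
}

# Independent quantile oracle: sort + linear interpolation between order
# statistics at position 1 + p*(n-1), written without stats::quantile.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- 1 + p * (n - 1)
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Brute-force retained-index enumeration for burn-in/thinning.
oracle_retained <- function(S, burnin, thin) {
  i <- seq_len(S) - 1L  # 0-based draw indices
  sum(i >= burnin & (i - burnin) %% thin == 0)
}

# A small GFF3 file with `n` genes on the given chromosome.
write_gff_fixture <- function(path, chrom = "chr1", n = 3,
                              starts = NULL, ends = NULL) {
  if (is.null(starts)) starts <- seq(100, by = 1000, length.out = n)
  if (is.null(ends)) ends <- starts + 200
  lines <- c(
    "##gff-version 3",
    sprintf("%s\ttest\tgene\t%d\t%d\t.\t+\t.\tID=g%d", chrom,
            starts, ends, seq_len(n)),
    sprintf("%s\ttest\texon\t%d\t%d\t.\t+\t.\tID=e%d", chrom,
            starts, pmin(ends, starts + 50), seq_len(n))
  )
  writeLines(lines, path)
  invisible(path)
}

# A minimal PAF file: one row per scaffold mapping.
write_paf_fixture <- function(path, rows) {
  lines <- vapply(rows, function(r) {
    paste(r$scaffold, r$scaffold_len, 0, r$scaffold_len, r$strand,
          r$chromosome, r$chrom_len, r$tstart, r$tstart + r$scaffold_len,
          r$scaffold_len, r$scaffold_len, r$mapq, sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
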
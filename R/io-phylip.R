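# IUPAC nucleotide ambiguity decoding. Two-base codes represent
# heterozygous SNP calls in concatenated-SNP alignments; three/four-base
# codes cannot be represented in a biallelic model and are read as missing.
IUPAC_PAIRS <- list(
  A = c("A", "A"), C = c("C", "C"), G = c("G", "G"), T = c("T", "T"),
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
  W = c("A", "T"), K = c("G", "T"), M = c("A", "C")
)
IUPAC_MISSING <- c("N", "-", "?")
IUPAC_MULTI <- c("B", "D", "H", "V")

#' Read a PHYLIP-formatted concatenated-SNP alignment
#'
#' Reads a sequential, relaxed-name PHYLIP alignment in which each column
#' is one SNP. Homozygotes are the plain bases A/C/G/T; heterozygotes are
#' two-base IUPAC ambiguity codes (R, Y, S, W, K, M); `N`, `-` and `?` are
#' missing. Three- and four-base ambiguity codes (B, D, H, V) cannot be
#' expressed as a biallelic diploid genotype and are treated as missing
#' with a warning.
#'
#' Per-locus alleles are inferred from the data: the first allele is the
#' base observed first when scanning samples top to bottom (heterozygote
#' codes contribute both bases in alphabetical order), and genotypes count
#' copies of the second allele. Loci where three or more distinct bases
#' are observed keep their full observed-allele count so the biallelic
#' filter can remove them, and their genotypes are set missing.
#'
#' @param path Path to the PHYLIP file. The first line must hold the
#'   sample count and sequence length.
#' @param popmap Path to a popmap file covering every sequence name.
#' @return A [genotype_matrix()].
#' @export
read_phylip <- function(path, popmap) {
  if (!file.exists(path)) abort("PHYLIP file not found: %s", path)
  pm <- read_popmap(popmap)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("empty PHYLIP file: %s", path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 2) abort("malformed PHYLIP header line: '%s'", lines[1])
  n_samp <- suppressWarnings(as.integer(hdr[1]))
  n_loci <- suppressWarnings(as.integer(hdr[2]))
  if (is.na(n_samp) || is.na(n_loci)) {
    abort("PHYLIP header must hold sample count and sequence length")
  }
  body <- lines[-1]
  if (length(body) != n_samp) {
    abort("PHYLIP header declares %d samples but body has %d lines",
          n_samp, length(body))
  }
  parts <- strsplit(trimws(body), "\\s+")
  names_ <- vapply(parts, `[`, character(1), 1)
  seqs <- vapply(parts, function(p) paste(p[-1], collapse = ""), character(1))
  lens <- nchar(seqs)
  if (any(lens != n_loci)) {
    bad <- which(lens != n_loci)[1]
    abort("sequence '%s' has length %d, header declares %d",
          names_[bad], lens[bad], n_loci)
  }
  pops <- popmap_labels(names_, pm)

  chars <- toupper(do.call(rbind, strsplit(seqs, "", fixed = TRUE)))
  if (any(chars %in% IUPAC_MULTI)) {
    warn("%d three/four-base IUPAC codes treated as missing",
         sum(chars %in% IUPAC_MULTI))
  }

  geno <- matrix(NA_integer_, nrow = n_samp, ncol = n_loci)
  alleles <- matrix(NA_character_, nrow = n_loci, ncol = 2)
  allele_count <- integer(n_loci)
  for (j in seq_len(n_loci)) {
    col <- chars[, j]
    obs <- character(0)  # alleles in order of first observation
    pairs <- vector("list", n_samp)
    for (i in seq_len(n_samp)) {
      b <- col[i]
      if (b %in% IUPAC_MISSING || b %in% IUPAC_MULTI) next
      pr <- IUPAC_PAIRS[[b]]
      if (is.null(pr)) abort("unrecognised base '%s' in sequence '%s'",
                             b, names_[i])
      pairs[[i]] <- pr
      for (a in unique(pr)) if (!(a %in% obs)) obs <- c(obs, a)
    }
    allele_count[j] <- length(obs)
    if (length(obs) >= 1) alleles[j, 1] <- obs[1]
    if (length(obs) >= 2) alleles[j, 2] <- obs[2]
    if (length(obs) > 2) next  # not biallelic: genotypes stay missing
    for (i in seq_len(n_samp)) {
      pr <- pairs[[i]]
      if (is.null(pr)) next
      geno[i, j] <- sum(pr == alleles[j, 2])
      if (length(obs) == 1) geno[i, j] <- 0L  # monomorphic: allele 1 only
    }
  }

  genotype_matrix(
    genotypes = geno,
    sample_ids = names_,
    pop_labels = pops,
    locus_ids = paste0("locus_", seq_len(n_loci)),
    alleles = alleles,
    allele_count = allele_count
  )
}
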
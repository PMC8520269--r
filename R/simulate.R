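#' Define ground truth for a simulated bgc posterior
#'
#' Fixes the per-locus true cline parameters, the outlier set, posterior
#' spread, per-individual hybrid indices, and the MCMC geometry used by
#' [simulate_bgc_posterior()]. Every draw the simulator emits is a pure
#' function of this object (including its seed).
#'
#' @param n_loci Number of loci.
#' @param true_alpha,true_beta Per-locus true parameter values (recycled;
#'   default all zero, i.e. neutral).
#' @param posterior_sd Spread of the simulated posterior around each true
#'   value (> 0).
#' @param hybrid_indices Per-admixed-individual true hybrid indices in
#'   (0, 1).
#' @param replicate_count,draws_per_replicate MCMC geometry.
#' @param sigma_prior Standard deviation of the zero-mean Gaussian
#'   conditional prior used to turn true values into prior quantiles.
#' @param lnl_phi Lag-1 autocorrelation of the simulated stationary AR(1)
#'   log-likelihood trace.
#' @param seed Integer seed; the same truth always yields byte-identical
#'   files.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(n_loci,
                             true_alpha = 0,
                             true_beta = 0,
                             posterior_sd = 0.2,
                             hybrid_indices = seq(0.1, 0.9,
                                                  length.out = 20),
                             replicate_count = 2,
                             draws_per_replicate = 1000,
                             sigma_prior = 1,
                             lnl_phi = 0.5,
                             seed = 42) {
  if (n_loci < 1) abort("n_loci must be >= 1")
  if (posterior_sd <= 0) abort("posterior_sd must be > 0")
  if (any(hybrid_indices <= 0 | hybrid_indices >= 1)) {
    abort("hybrid_indices must lie strictly inside (0, 1)")
  }
  true_alpha <- rep_len(true_alpha, n_loci)
  true_beta <- rep_len(true_beta, n_loci)
  structure(
    list(n_loci = as.integer(n_loci),
         true_alpha = true_alpha, true_beta = true_beta,
         outlier_set = which(true_alpha != 0 | true_beta != 0),
         posterior_sd = posterior_sd,
         hybrid_indices = hybrid_indices,
         replicate_count = as.integer(replicate_count),
         draws_per_replicate = as.integer(draws_per_replicate),
         sigma_prior = sigma_prior,
         lnl_phi = lnl_phi,
         seed = as.integer(seed)),
    class = "simulation_truth"
  )
}

#' Simulate estpost-style bgc posterior output files
#'
#' Writes one file per parameter and replicate, named
#' `<prefix>_stat_<param>_<replicate>`, in the comma-separated
#' draws-as-rows dialect accepted by [parse_estpost_file()].
#'
#' Estimation noise is part of the emulation: each locus first draws a
#' point estimate once as Normal(true value, `posterior_sd`) — the
#' analysis of a finite dataset does not centre the posterior on the
#' truth — and the MCMC draws then scatter around that point estimate
#' with the same spread. This makes the simulated posteriors calibrated
#' in the frequentist sense: for a true-zero locus, the `level` credible
#' interval excludes zero with probability about `1 - level`, so
#' downstream type-I behaviour of the outlier rules can be measured.
#' Draws are generated as:
#' \itemize{
#'   \item `alpha`, `beta`: Normal(point estimate, posterior_sd) per
#'     locus, point estimates shared across replicates;
#'   \item `hi`: Beta draws concentrated around each admixed individual's
#'     true hybrid index;
#'   \item `LnL`: a stationary AR(1) series (autocorrelation `lnl_phi`);
#'   \item `gamma-quantile` / `zeta-quantile`: the point estimate's
#'     quantile within the Normal(0, `sigma_prior`) conditional prior,
#'     plus small Gaussian noise, clipped to \[0, 1\].
#' }
#' Draws are iid across iterations (an MCMC chain's autocorrelation is
#' emulated only in the LnL trace); this is sufficient to exercise
#' burn-in, thinning, interval, and outlier logic downstream.
#'
#' @param truth A [simulation_truth()].
#' @param outdir Output directory.
#' @param prefix File-name prefix shared by all replicates.
#' @return Character vector of written file paths, invisibly.
#' @export
simulate_bgc_posterior <- function(truth, outdir, prefix = "sim") {
  stopifnot(inherits(truth, "simulation_truth"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, 2) != 0) abort("outdir not writable: %s", outdir)

  paths <- character(0)
  with_seed(truth$seed, {
    S <- truth$draws_per_replicate
    L <- truth$n_loci
    n_ind <- length(truth$hybrid_indices)
    kappa <- 50  # Beta concentration of the hybrid-index posterior
    # per-locus point estimates: estimation noise around the truth,
    # shared by every replicate (replicates re-analyse the same data)
    alpha_hat <- stats::rnorm(L, truth$true_alpha, truth$posterior_sd)
    beta_hat <- stats::rnorm(L, truth$true_beta, truth$posterior_sd)
    gq_true <- stats::pnorm(alpha_hat, 0, truth$sigma_prior)
    zq_true <- stats::pnorm(beta_hat, 0, truth$sigma_prior)
    for (r in seq_len(truth$replicate_count)) {
      draws <- list(
        alpha = matrix(stats::rnorm(S * L,
                                    mean = rep(alpha_hat, each = S),
                                    sd = truth$posterior_sd),
                       nrow = S),
        beta = matrix(stats::rnorm(S * L,
                                   mean = rep(beta_hat, each = S),
                                   sd = truth$posterior_sd),
                      nrow = S),
        hi = matrix(stats::rbeta(S * n_ind,
                                 shape1 = rep(truth$hybrid_indices * kappa,
                                              each = S),
                                 shape2 = rep((1 - truth$hybrid_indices) *
                                                kappa, each = S)),
                    nrow = S),
        LnL = matrix(ar1_series(S, truth$lnl_phi, mean = -1000, sd = 5),
                     ncol = 1),
        `gamma-quantile` = matrix(
          pmin(pmax(stats::rnorm(S * L, mean = rep(gq_true, each = S),
                                 sd = 0.01), 0), 1), nrow = S),
        `zeta-quantile` = matrix(
          pmin(pmax(stats::rnorm(S * L, mean = rep(zq_true, each = S),
                                 sd = 0.01), 0), 1), nrow = S)
      )
      for (p in names(draws)) {
        path <- file.path(outdir, sprintf("%s_stat_%s_%d", prefix, p, r))
        m <- draws[[p]]
        writeLines(apply(format(m, digits = 15, trim = TRUE,
                                scientific = FALSE),
                         1, paste, collapse = ","), path)
        paths <- c(paths, path)
      }
    }
  })
  invisible(paths)
}

# Stationary AR(1) series: x_t = phi x_{t-1} + e_t scaled to the target
# marginal mean/sd, initialized from the stationary distribution.
ar1_series <- function(n, phi, mean = 0, sd = 1) {
  e <- stats::rnorm(n)
  x <- numeric(n)
  x[1] <- e[1]
  for (t in seq_len(n)[-1]) {
    x[t] <- phi * x[t - 1] + sqrt(1 - phi^2) * e[t]
  }
  mean + sd * x
}

#' Simulate a genotype dataset with known truth in three serializations
#'
#' Draws parental and admixed diploid genotypes at biallelic SNPs and
#' writes the same matrix as a VCF (with simulated allele depths), a
#' PHYLIP concatenated-SNP alignment (heterozygotes as IUPAC codes), and a
#' popmap — the substrate for format round-trip verification. Parental
#' genotypes are Binomial(2, population allele frequency); each admixed
#' individual draws a hybrid index `h ~ Uniform(0.1, 0.9)` and genotypes
#' Binomial(2, `h * p1 + (1 - h) * p0`). Missing calls are sprinkled at
#' `missing_rate`. Allele depths are `(2 - g) * depth_per_copy` REF and
#' `g * depth_per_copy` ALT reads.
#'
#' @param n_p0,n_p1,n_admixed Sample sizes per population.
#' @param n_loci Number of SNPs.
#' @param p0_freqs,p1_freqs Per-locus ALT allele frequencies in the two
#'   parental populations (recycled). Defaults make loci strongly
#'   differentiated (0.1 vs 0.9), the informative case for cline input.
#' @param missing_rate Per-call missing probability.
#' @param seed Integer seed; generation is a pure function of it.
#' @param outdir Directory for the serialized files.
#' @param prefix File-name prefix.
#' @param depth_per_copy Simulated reads per allele copy in the VCF AD
#'   field.
#' @return A list: `genotypes` (the true [genotype_matrix()]), `vcf`,
#'   `phylip`, `popmap` (paths), and `truth` (per-individual hybrid
#'   indices and per-locus frequencies).
#' @export
simulate_genotype_data <- function(n_p0 = 10, n_p1 = 10, n_admixed = 20,
                                   n_loci = 50,
                                   p0_freqs = 0.1, p1_freqs = 0.9,
                                   missing_rate = 0, seed = 42,
                                   outdir = tempfile("simgeno"),
                                   prefix = "sim",
                                   depth_per_copy = 5L) {
  if (any(p0_freqs < 0 | p0_freqs > 1) || any(p1_freqs < 0 | p1_freqs > 1)) {
    abort("allele frequencies must lie in [0, 1]")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("missing_rate must lie in [0, 1)")
  }
  p0_freqs <- rep_len(p0_freqs, n_loci)
  p1_freqs <- rep_len(p1_freqs, n_loci)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  with_seed(seed, {
    n <- n_p0 + n_p1 + n_admixed
    h <- stats::runif(n_admixed, 0.1, 0.9)
    geno <- matrix(NA_integer_, nrow = n, ncol = n_loci)
    for (j in seq_len(n_loci)) {
      geno[seq_len(n_p0), j] <- stats::rbinom(n_p0, 2, p0_freqs[j])
      geno[n_p0 + seq_len(n_p1), j] <- stats::rbinom(n_p1, 2, p1_freqs[j])
      pa <- h * p1_freqs[j] + (1 - h) * p0_freqs[j]
      geno[n_p0 + n_p1 + seq_len(n_admixed), j] <-
        stats::rbinom(n_admixed, 2, pa)
    }
    if (missing_rate > 0) {
      drop <- matrix(stats::runif(n * n_loci) < missing_rate,
                     nrow = n)
      geno[drop] <- NA_integer_
    }
    # distinct REF/ALT bases per locus
    ref <- sample(c("A", "C", "G", "T"), n_loci, replace = TRUE)
    alt <- vapply(ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1)
    }, character(1))

    sample_ids <- c(sprintf("p0_%02d", seq_len(n_p0)),
                    sprintf("p1_%02d", seq_len(n_p1)),
                    sprintf("adm_%02d", seq_len(n_admixed)))
    pops <- c(rep("P0", n_p0), rep("P1", n_p1), rep("ADMIXED", n_admixed))
    locus_ids <- paste0("locus_", seq_len(n_loci))
    chrom <- rep("scaffold_1", n_loci)
    pos <- seq_len(n_loci) * 1000L

    gm <- genotype_matrix(geno, sample_ids, pops, locus_ids,
                          alleles = cbind(ref, alt),
                          chrom = chrom, pos = pos)

    popmap_path <- file.path(outdir, paste0(prefix, ".popmap"))
    writeLines(paste(sample_ids, pops, sep = "\t"), popmap_path)

    vcf_path <- file.path(outdir, paste0(prefix, ".vcf"))
    write_simple_vcf(gm, vcf_path, depth_per_copy)

    phylip_path <- file.path(outdir, paste0(prefix, ".phy"))
    write_simple_phylip(gm, phylip_path)

    list(genotypes = gm, vcf = vcf_path, phylip = phylip_path,
         popmap = popmap_path,
         truth = list(hybrid_indices = h, p0_freqs = p0_freqs,
                      p1_freqs = p1_freqs, seed = seed))
  })
}

# Minimal VCF 4.2 writer for simulated biallelic SNPs with GT:AD.
write_simple_vcf <- function(gm, path, depth_per_copy = 5L) {
  n <- length(gm$sample_ids)
  m <- length(gm$locus_ids)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t")
  )
  gt_str <- c("0/0", "0/1", "1/1")
  rows <- vapply(seq_len(m), function(j) {
    cells <- vapply(seq_len(n), function(i) {
      g <- gm$genotypes[i, j]
      if (is.na(g)) return("./.:.")
      sprintf("%s:%d,%d", gt_str[g + 1],
              (2L - g) * depth_per_copy, g * depth_per_copy)
    }, character(1))
    paste(c(gm$chrom[j], gm$pos[j], gm$locus_ids[j],
            gm$alleles[j, 1], gm$alleles[j, 2], ".", "PASS", ".",
            "GT:AD", cells), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# IUPAC code for an unordered base pair.
iupac_code <- local({
  codes <- character(0)
  for (code in names(IUPAC_PAIRS)) {
    pr <- sort(IUPAC_PAIRS[[code]])
    codes[paste(pr, collapse = "")] <- code
  }
  codes
})

# Minimal sequential relaxed-name PHYLIP writer.
write_simple_phylip <- function(gm, path) {
  n <- length(gm$sample_ids)
  m <- length(gm$locus_ids)
  seqs <- vapply(seq_len(n), function(i) {
    paste(vapply(seq_len(m), function(j) {
      g <- gm$genotypes[i, j]
      if (is.na(g)) return("N")
      a <- gm$alleles[j, ]
      pair <- sort(c(rep(a[1], 2L - g), rep(a[2], g))[c(1, 2)])
      iupac_code[[paste(pair, collapse = "")]]
    }, character(1)), collapse = "")
  }, character(1))
  writeLines(c(paste(n, m), paste(gm$sample_ids, seqs)), path)
  invisible(path)
}

#' Compare two genotype matrices up to per-locus allele order
#'
#' Serializations that infer allele order from the data (PHYLIP) may list
#' a locus's alleles in the opposite order from the generating matrix; the
#' genotype coding then flips 0 <-> 2. This helper tests equality of
#' genotype content after aligning each locus's allele order to the
#' reference matrix.
#'
#' @param gm,ref Two [genotype_matrix()] objects with identical dimensions
#'   and sample order.
#' @return `TRUE` if equal up to allele order, otherwise a character
#'   description of the first difference.
#' @export
same_genotypes <- function(gm, ref) {
  if (!identical(dim(gm$genotypes), dim(ref$genotypes))) {
    return(sprintf("dimensions differ: %s vs %s",
                   paste(dim(gm$genotypes), collapse = "x"),
                   paste(dim(ref$genotypes), collapse = "x")))
  }
  g <- gm$genotypes
  for (j in seq_len(ncol(g))) {
    a <- gm$alleles[j, ]
    b <- ref$alleles[j, ]
    if (!anyNA(a) && !anyNA(b) && a[1] == b[2] && a[2] == b[1]) {
      g[, j] <- 2L - g[, j]
    } else if (is.na(a[2]) && !is.na(a[1]) && !anyNA(b) && a[1] == b[2]) {
      # only one allele observed, and it is the reference matrix's second:
      # the inferred coding counts the wrong allele
      g[, j] <- 2L - g[, j]
    } else if (!anyNA(a) && !anyNA(b) && !all(a == b) &&
               length(intersect(a, b)) < 2 && !all(is.na(g[, j]))) {
      return(sprintf("locus %d alleles disagree: %s/%s vs %s/%s",
                     j, a[1], a[2], b[1], b[2]))
    }
  }
  if (identical(g, ref$genotypes)) TRUE
  else {
    d <- which(g != ref$genotypes | xor(is.na(g), is.na(ref$genotypes)))[1]
    sprintf("first genotype difference at flat index %d", d)
  }
}
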
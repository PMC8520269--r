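# Input parsing, filtering, and the bgc/Introgress writers.

test_that("read_vcf parses a single-sample heterozygote with depths", {
  td <- withr::local_tempdir()
  vcf <- file.path(td, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    paste(c("scaf1", "100", "snp1", "A", "C", ".", "PASS", ".",
            "GT:AD", "0/1:3,5"), collapse = "\t"),
    paste(c("scaf1", "200", "snp2", "G", "T", ".", "PASS", ".",
            "GT:AD", "./.:."), collapse = "\t")
  ), vcf)
  pm <- file.path(td, "popmap")
  writeLines("s1\tpopA", pm)
  res <- read_vcf(vcf, pm)
  expect_identical(res$genotypes$genotypes[1, ], c(1L, NA_integer_))
  expect_identical(res$genotypes$pop_labels, "popA")
  expect_identical(res$read_counts$counts1[1, 1], 3L)
  expect_identical(res$read_counts$counts2[1, 1], 5L)
  expect_true(is.na(res$read_counts$counts1[1, 2]))
  expect_identical(res$genotypes$chrom, c("scaf1", "scaf1"))
  expect_identical(res$genotypes$pos, c(100L, 200L))
})

test_that("read_vcf errors when a VCF sample is absent from the popmap", {
  sg <- simulate_genotype_data(n_loci = 5, seed = 2,
                               outdir = withr::local_tempdir())
  pm2 <- tempfile()
  pmap <- utils::read.table(sg$popmap, col.names = c("s", "p"))
  writeLines(paste(pmap$s[-1], pmap$p[-1], sep = "\t"), pm2)
  expect_error(read_vcf(sg$vcf, pm2), pmap$s[1])
})

test_that("read_phylip decodes IUPAC heterozygotes and missing codes", {
  td <- withr::local_tempdir()
  phy <- file.path(td, "toy.phy")
  # s1 = AA at locus 1, A at locus 2; s2 het R = A/G at locus 2
  writeLines(c("3 2", "s1 AA", "s2 AR", "s3 NN"), phy)
  pm <- file.path(td, "popmap")
  writeLines(c("s1\tP0", "s2\tP1", "s3\tADM"), pm)
  gm <- read_phylip(phy, pm)
  expect_identical(gm$genotypes[, 2], c(0L, 1L, NA))   # A/A, A/G, N
  expect_identical(gm$alleles[2, ], c("A", "G"))
  expect_true(all(is.na(gm$genotypes[3, ])))
})

test_that("read_phylip rejects dimension mismatches and warns on B/D/H/V", {
  td <- withr::local_tempdir()
  pm <- file.path(td, "popmap")
  writeLines(c("s1\tP0", "s2\tP1"), pm)
  phy <- file.path(td, "bad.phy")
  writeLines(c("2 3", "s1 AAA", "s2 AA"), phy)
  expect_error(read_phylip(phy, pm), "length")
  phy2 <- file.path(td, "multi.phy")
  writeLines(c("2 2", "s1 AB", "s2 AA"), phy2)
  expect_warning(gm <- read_phylip(phy2, pm), "missing")
  expect_true(is.na(gm$genotypes[1, 2]))
})

test_that("filter_genotypes removes exactly the hand-enumerated loci", {
  gm <- toy_filter_matrix()
  spec <- filter_spec(max_missing_per_locus = 0.25, min_maf = 0.15,
                      biallelic_only = TRUE, drop_monomorphic = TRUE)
  res <- filter_genotypes(gm, spec)
  expect_identical(res$genotypes$locus_ids, "L1")
  rep_counts <- stats::setNames(res$report$removed, res$report$stage)
  expect_identical(rep_counts[["non_biallelic"]], 1L)
  expect_identical(rep_counts[["monomorphic"]], 1L)
  expect_identical(rep_counts[["locus_missing"]], 1L)
  expect_identical(rep_counts[["maf"]], 1L)
  expect_identical(rep_counts[["individual_missing"]], 0L)
  # locus-dropping stage counts account for every removed locus
  locus_stages <- setdiff(res$report$stage, "individual_missing")
  expect_identical(sum(rep_counts[locus_stages]),
                   ncol(gm$genotypes) - ncol(res$genotypes$genotypes))
})

test_that("disabled filters are the identity and subsampling is seeded", {
  gm <- toy_filter_matrix()
  off <- filter_spec(max_missing_per_locus = 1,
                     max_missing_per_individual = 1, min_maf = 0,
                     biallelic_only = FALSE, drop_monomorphic = FALSE)
  res <- filter_genotypes(gm, off)
  expect_identical(res$genotypes$genotypes, gm$genotypes)
  expect_identical(res$genotypes$locus_ids, gm$locus_ids)

  sub <- filter_spec(biallelic_only = FALSE, drop_monomorphic = FALSE,
                     subsample_n = 1, seed = 99)
  r1 <- filter_genotypes(gm, sub)
  r2 <- filter_genotypes(gm, sub)
  expect_identical(r1$genotypes$locus_ids, r2$genotypes$locus_ids)
  expect_length(r1$genotypes$locus_ids, 1)
})

test_that("filtered output never violates an enabled rule", {
  sg <- simulate_genotype_data(n_loci = 80, missing_rate = 0.2, seed = 5,
                               outdir = withr::local_tempdir())
  spec <- filter_spec(max_missing_per_locus = 0.2,
                      max_missing_per_individual = 0.3, min_maf = 0.1)
  res <- filter_genotypes(sg$genotypes, spec)
  g <- res$genotypes$genotypes
  expect_true(all(colMeans(is.na(g)) <= 0.2))
  expect_true(all(rowMeans(is.na(g)) <= 0.3))
  maf <- apply(g, 2, function(col) {
    col <- col[!is.na(col)]
    p <- sum(col) / (2 * length(col))
    min(p, 1 - p)
  })
  expect_true(all(maf >= 0.1))
  expect_true(all(res$genotypes$allele_count <= 2))
})

test_that("filtering everything fails loudly naming the stage", {
  gm <- genotype_matrix(
    rbind(c(NA, 0L), c(1L, NA)),
    sample_ids = c("a", "b"), pop_labels = c("P0", "P1"),
    locus_ids = c("l1", "l2")
  )
  spec <- filter_spec(max_missing_per_locus = 0, biallelic_only = FALSE,
                      drop_monomorphic = FALSE)
  expect_error(filter_genotypes(gm, spec), "locus_missing")
})

test_that("bgc genotype lines encode allele copy counts and missing as -9", {
  gm <- genotype_matrix(
    rbind(c(0L, 1L), c(2L, NA), c(1L, 1L)),
    sample_ids = c("a", "b", "c"),
    pop_labels = c("P0", "P1", "ADMIXED"),
    locus_ids = c("l1", "l2"),
    alleles = cbind(c("A", "G"), c("C", "T"))
  )
  td <- withr::local_tempdir()
  paths <- write_bgc_input(gm, td)
  expect_identical(readLines(paths[["parental0"]]),
                   c("locus_1", "2 0", "locus_2", "1 1"))
  expect_identical(readLines(paths[["parental1"]]),
                   c("locus_1", "0 2", "locus_2", "-9 -9"))
  expect_identical(readLines(paths[["admixed"]]),
                   c("locus_1", "pop_1", "1 1", "locus_2", "pop_1", "1 1"))
})

test_that("bgc writer/reader round-trips simulated matrices exactly", {
  sg <- simulate_genotype_data(n_loci = 30, missing_rate = 0.1, seed = 11,
                               outdir = withr::local_tempdir())
  td <- withr::local_tempdir()
  paths <- write_bgc_input(sg$genotypes, td)
  back <- read_bgc_input(paths[["parental0"]], paths[["parental1"]],
                         paths[["admixed"]])
  expect_identical(back$genotypes, sg$genotypes$genotypes)
  # population structure preserved up to synthesized names
  expect_identical(table(back$pop_labels)[["P0"]],
                   sum(sg$genotypes$pop_labels == "P0"))
})

test_that("bgc read-count mode writes depths and requires counts", {
  sg <- simulate_genotype_data(n_loci = 4, seed = 8,
                               outdir = withr::local_tempdir())
  rc <- read_vcf(sg$vcf, sg$popmap)$read_counts
  td <- withr::local_tempdir()
  paths <- write_bgc_input(sg$genotypes, td, mode = "readcount", rc = rc)
  first_data <- readLines(paths[["parental0"]])[2]
  expect_match(first_data, "^\\d+ \\d+$")
  expect_error(write_bgc_input(sg$genotypes, td, mode = "readcount"),
               "read_count")
})

test_that("read_bgc_input rejects inconsistent or empty inputs", {
  td <- withr::local_tempdir()
  p0 <- file.path(td, "p0"); p1 <- file.path(td, "p1")
  adm <- file.path(td, "adm")
  writeLines(c("locus_1", "2 0"), p0)
  writeLines(c("locus_1", "0 2", "locus_2", "0 2"), p1)
  writeLines(c("locus_1", "pop_1", "1 1"), adm)
  expect_error(read_bgc_input(p0, p1, adm), "locus counts")
  writeLines(c("locus_1", "0 2"), p1)
  writeLines("locus_1", adm)
  expect_error(read_bgc_input(p0, p1, adm), "empty")
  writeLines(c("locus_1", "pop_1", "-9 -9"), adm)
  back <- read_bgc_input(p0, p1, adm)
  expect_true(is.na(back$genotypes[3, 1]))
})

test_that("Introgress export writes allele pairs, NA/NA, and a loci table", {
  gm <- genotype_matrix(
    rbind(c(1L, 0L), c(0L, 2L), c(2L, NA)),
    sample_ids = c("a", "b", "c"),
    pop_labels = c("ADMIXED", "P0", "P1"),
    locus_ids = c("l1", "l2"),
    alleles = cbind(c("A", "G"), c("C", "T"))
  )
  td <- withr::local_tempdir()
  paths <- write_introgress_input(gm, td)
  adm <- readLines(paths[["admix"]])
  # two header rows (pops, ids) then loci as rows
  expect_identical(adm[1], "ADMIXED")
  expect_identical(adm[2], "a")
  expect_identical(adm[3], "A/C")
  p2 <- readLines(paths[["parental2"]])
  expect_identical(p2[3], "C/C")
  expect_identical(p2[4], "NA/NA")
  loci <- utils::read.csv(paths[["loci"]])
  expect_identical(nrow(loci), 2L)
  expect_true(all(loci$type == "C"))
})
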
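# Scaffold-to-chromosome lifting, gene joins, ideogram bands.

test_that("parse_gff keeps gene intervals with IDs and drops other features", {
  td <- withr::local_tempdir()
  gff <- file.path(td, "genes.gff3")
  write_gff_fixture(gff, chrom = "chr1", n = 5)
  genes <- parse_gff(gff)
  expect_identical(nrow(genes), 5L)
  expect_identical(genes$seqid[1], "chr1")
  expect_identical(genes$gene_id, paste0("g", 1:5))
  expect_identical(genes$start[1], 100L)
  expect_identical(genes$end[1], 300L)
  expect_true(all(genes$strand == "+"))
})

test_that("parse_scaffold_map shifts PAF coordinates and keeps the best hit", {
  td <- withr::local_tempdir()
  paf <- file.path(td, "map.paf")
  writeLines(c(
    # scafA maps twice: quality 60 (tstart 999) beats quality 30
    paste("scafA", 200, 0, 200, "+", "chr1", 10000, 999, 1199, 200, 200, 60,
          sep = "\t"),
    paste("scafA", 200, 0, 200, "+", "chr2", 10000, 0, 200, 200, 200, 30,
          sep = "\t"),
    paste("scafB", 300, 0, 300, "-", "chr1", 10000, 4999, 5299, 300, 300, 55,
          sep = "\t"),
    paste("scafC", 150, 0, 150, "+", "chr2", 8000, 49, 199, 150, 150, 60,
          sep = "\t")
  ), paf)
  m <- parse_scaffold_map(paf, dialect = "paf")
  expect_identical(nrow(m), 3L)
  a <- m[m$scaffold == "scafA", ]
  expect_identical(a$chromosome, "chr1")       # quality-60 hit retained
  expect_identical(a$chrom_start, 1000L)       # 0-based 999 -> 1-based 1000
  expect_identical(m$orientation[m$scaffold == "scafB"], "-")
})

test_that("PAF quality ties break by longest alignment block", {
  td <- withr::local_tempdir()
  paf <- file.path(td, "tie.paf")
  writeLines(c(
    paste("s", 500, 0, 100, "+", "chr1", 1e4, 0, 100, 100, 100, 60,
          sep = "\t"),
    paste("s", 500, 0, 400, "+", "chr2", 1e4, 0, 400, 400, 400, 60,
          sep = "\t")
  ), paf)
  m <- parse_scaffold_map(paf, dialect = "paf")
  expect_identical(m$chromosome, "chr2")
})

test_that("coordinate lifting follows the orientation formulas", {
  mapping <- data.frame(
    scaffold = c("f", "r"), scaffold_len = c(500L, 200L),
    chromosome = c("chr1", "chr1"), chrom_start = c(1000L, 1000L),
    orientation = c("+", "-"), mapping_quality = c(60L, 60L)
  )
  # forward: chrom_start + pos - 1
  expect_identical(lift_coordinates("f", 50, mapping)$chrom_pos, 1049L)
  expect_identical(lift_coordinates("f", 1, mapping)$chrom_pos, 1000L)
  # reverse: chrom_start + (len - pos)
  expect_identical(lift_coordinates("r", 50, mapping)$chrom_pos, 1150L)
  # unplaced scaffolds pass through as UNPLACED, not an error
  got <- lift_coordinates("nope", 10, mapping)
  expect_identical(got$chromosome, "UNPLACED")
  expect_true(is.na(got$chrom_pos))
  expect_error(lift_coordinates("f", 501, mapping), "out of range")
})

test_that("lifting round-trips 1000 random SNPs exactly and is injective", {
  withr::with_seed(42, {
    n_scaf <- 20
    mapping <- data.frame(
      scaffold = paste0("s", seq_len(n_scaf)),
      scaffold_len = sample(1000:50000, n_scaf),
      chromosome = sample(paste0("chr", 1:3), n_scaf, replace = TRUE),
      chrom_start = sample(1:10000000, n_scaf),
      orientation = sample(c("+", "-"), n_scaf, replace = TRUE),
      mapping_quality = 60L
    )
    scafs <- sample(mapping$scaffold, 1000, replace = TRUE)
    pos <- vapply(scafs, function(s) {
      sample(mapping$scaffold_len[mapping$scaffold == s], 1)
    }, integer(1))
    lifted <- lift_coordinates(scafs, pos, mapping)
    expect_identical(unlift_coordinates(scafs, lifted$chrom_pos, mapping),
                     unname(pos))
    # injectivity per scaffold
    for (s in unique(scafs)) {
      i <- scafs == s
      expect_identical(anyDuplicated(lifted$chrom_pos[i][
        !duplicated(pos[i])]), 0L)
    }
  })
})

test_that("gene joins flag SNPs inside intervals with deterministic ties", {
  genes <- data.frame(
    seqid = c("chr1", "chr1", "chr1"),
    start = c(100L, 140L, 400L), end = c(200L, 260L, 500L),
    strand = "+", gene_id = c("gA", "gB", "gC"),
    stringsAsFactors = FALSE
  )
  mapping <- data.frame(
    scaffold = "s1", scaffold_len = 1000L, chromosome = "chr1",
    chrom_start = 1L, orientation = "+", mapping_quality = 60L
  )
  snps <- data.frame(
    locus = c("in_one", "in_overlap", "outside", "unplaced"),
    scaffold = c("s1", "s1", "s1", "zz"),
    scaffold_pos = c(150L, 150L, 300L, 10L),
    alpha = 1:4 / 10, beta = 0,
    stringsAsFactors = FALSE
  )
  ann <- join_outliers_to_genes(snps, genes, mapping)
  expect_true(ann$in_gene[1])
  # overlap tie resolved to the lowest start coordinate
  expect_identical(ann$gene_id[2], "gA")
  expect_false(ann$in_gene[3])
  expect_identical(ann$chromosome[4], "UNPLACED")
  expect_false(ann$in_gene[4])
  expect_true(is.na(ann$gene_id[4]))
})

test_that("ideogram bands are centred, width-coded, and clipped", {
  ann <- data.frame(
    locus = c("a", "b", "c"),
    scaffold = "s", scaffold_pos = 1L,
    chromosome = c("chr1", "chr1", "chr1"),
    chrom_pos = c(5000L, 100L, 9999900L),
    in_gene = c(TRUE, FALSE, FALSE),
    gene_id = c("g", NA, NA),
    alpha = c(1.5, -0.2, 0.4), beta = 0,
    stringsAsFactors = FALSE
  )
  kar <- data.frame(chromosome = "chr1", length = 1e7)
  bands <- ideogram_bands(ann, kar, param = "alpha",
                          gene_band_bp = 2000, nongene_band_bp = 500)
  expect_equal(bands$band_start[1], 4000)  # in-gene: centred, width 2000
  expect_equal(bands$band_end[1], 6000)
  expect_equal(bands$band_start[2], 1)     # clipped at chromosome start
  expect_equal(bands$band_end[3], 1e7)     # clipped at chromosome end
  expect_equal(bands$value, ann$alpha)
  expect_true(all(bands$band_start >= 1 & bands$band_end <= 1e7))
  # missing chromosome in the karyotype is an error
  ann2 <- ann; ann2$chromosome <- "chrX"
  expect_error(ideogram_bands(ann2, kar), "chrX")
  # zero placed SNPs yield an empty table
  ann3 <- ann; ann3$chromosome <- "UNPLACED"
  expect_identical(nrow(ideogram_bands(ann3, kar)), 0L)
})

test_that("the full genome-map pipeline produces in-bound bands and a figure", {
  td <- withr::local_tempdir()
  gff <- write_gff_fixture(file.path(td, "g.gff3"), chrom = "chr1", n = 3,
                           starts = c(100000, 300000, 700000))
  paf <- file.path(td, "m.paf")
  writeLines(c(
    paste("scaf1", 5e5, 0, 5e5, "+", "chr1", 2e6, 0, 5e5, 5e5, 5e5, 60,
          sep = "\t"),
    paste("scaf2", 4e5, 0, 4e5, "-", "chr2", 1e6, 99999, 499999, 4e5, 4e5,
          60, sep = "\t")
  ), paf)
  genes <- parse_gff(gff)
  mapping <- parse_scaffold_map(paf)
  snps <- data.frame(
    locus = paste0("l", 1:6),
    scaffold = rep(c("scaf1", "scaf2"), each = 3),
    scaffold_pos = c(100050L, 250000L, 399999L, 1L, 200000L, 400000L),
    alpha = rnorm(6), beta = rnorm(6), stringsAsFactors = FALSE
  )
  ann <- join_outliers_to_genes(snps, genes, mapping)
  expect_true(ann$in_gene[1])  # scaf1:100050 -> chr1:100050 inside gene 1
  kar <- data.frame(chromosome = c("chr1", "chr2"), length = c(2e6, 1e6))
  ab <- ideogram_bands(ann, kar, "alpha")
  bb <- ideogram_bands(ann, kar, "beta")
  expect_true(all(ab$band_start >= 1))
  for (ch in unique(ab$chromosome)) {
    expect_true(all(ab$band_end[ab$chromosome == ch] <=
                      kar$length[kar$chromosome == ch]))
  }
  fig <- file.path(td, "ideo.svg")
  save_figure(plot_outlier_ideogram(ab, bb, kar), fig)
  expect_gt(file.size(fig), 0)
})
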
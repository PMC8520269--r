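# Replicate discovery, estpost parsing, burn-in/thinning, traces.

test_that("discover_replicates groups and orders files by parameter", {
  td <- withr::local_tempdir()
  for (f in c("run_stat_alpha_1", "run_stat_alpha_2",
              "run_stat_beta_1", "run_stat_beta_2",
              "run_stat_LnL_01")) {
    file.create(file.path(td, f))
  }
  got <- discover_replicates(td, "run")
  expect_setequal(names(got), c("alpha", "beta", "LnL"))
  expect_identical(basename(got$alpha),
                   c("run_stat_alpha_1", "run_stat_alpha_2"))
  # zero-padded replicate parses as an integer
  expect_identical(basename(got$LnL), "run_stat_LnL_01")
})

test_that("discover_replicates errors on alpha/beta replicate mismatch", {
  td <- withr::local_tempdir()
  for (f in c("run_stat_alpha_1", "run_stat_alpha_2", "run_stat_beta_1")) {
    file.create(file.path(td, f))
  }
  expect_error(discover_replicates(td, "run"), "beta")
})

test_that("unknown parameter names pass through with a warning", {
  td <- withr::local_tempdir()
  file.create(file.path(td, "run_stat_mystery_1"))
  expect_warning(got <- discover_replicates(td, "run"), "mystery")
  expect_identical(names(got), "mystery")
})

test_that("parse_estpost_file normalizes both orientations", {
  td <- withr::local_tempdir()
  path <- file.path(td, "f")
  writeLines(c("0.1,0.2,0.3", "-0.1,0.0,0.1"), path)
  # entities-as-rows: 2 entities, 3 draws, entity 1 = (0.1, 0.2, 0.3)
  m <- parse_estpost_file(path, orientation = "entities_as_rows")
  expect_identical(dim(m), c(3L, 2L))
  expect_equal(m[, 1], c(0.1, 0.2, 0.3))
  # samples-as-rows: 2 draws x 3 entities
  m2 <- parse_estpost_file(path, orientation = "samples_as_rows")
  expect_identical(dim(m2), c(2L, 3L))
  # header handling
  writeLines(c("h1,h2", "1,2"), path)
  expect_identical(dim(parse_estpost_file(path, has_header = TRUE)),
                   c(1L, 2L))
})

test_that("parse_estpost_file rejects ragged and non-numeric input", {
  td <- withr::local_tempdir()
  path <- file.path(td, "f")
  writeLines(c("1,2,3", "1,2"), path)
  expect_error(parse_estpost_file(path), "ragged row 2")
  writeLines(c("1,2", "1,x"), path)
  expect_error(parse_estpost_file(path), "non-numeric")
})

test_that("burn-in and thinning retain the documented index set", {
  td <- withr::local_tempdir()
  # two replicates of 1000 draws each over 3 loci
  with_vals <- lapply(1:2, function(r) {
    matrix(seq_len(1000 * 3) + r * 1e5, nrow = 1000)
  })
  write_estpost_fixture(td, "run", "alpha", with_vals)
  write_estpost_fixture(td, "run", "beta", with_vals)
  ps <- combine_bgc_output(td, burnin = 200, thin = 2, prefix = "run")
  expect_identical(nrow(ps$params$alpha$samples), 800L)
  expect_identical(as.integer(table(ps$params$alpha$replicate)),
                   c(400L, 400L))
  # first retained draw of each replicate is draw index 201 (1-based)
  expect_equal(ps$params$alpha$samples[1, 1], with_vals[[1]][201, 1])
  expect_equal(ps$params$alpha$samples[401, 1], with_vals[[2]][201, 1])
  # stride anchored at the burn-in point
  expect_equal(ps$params$alpha$samples[2, 1], with_vals[[1]][203, 1])
})

test_that("no burn-in and thin 1 is plain concatenation; edge burn-in keeps 1", {
  td <- withr::local_tempdir()
  m <- matrix(rnorm(50), nrow = 25)
  write_estpost_fixture(td, "x", "alpha", list(m))
  write_estpost_fixture(td, "x", "beta", list(m))
  ps <- combine_bgc_output(td, burnin = 0, thin = 1, prefix = "x")
  expect_equal(ps$params$alpha$samples, m)
  ps2 <- combine_bgc_output(td, burnin = 24, thin = 1, prefix = "x")
  expect_identical(nrow(ps2$params$alpha$samples), 1L)
  expect_error(combine_bgc_output(td, burnin = 25, prefix = "x"),
               "burnin")
})

test_that("retained counts match brute-force enumeration over a sweep", {
  td <- withr::local_tempdir()
  for (S in c(1, 7, 23, 50)) {
    m <- matrix(seq_len(S), ncol = 1)
    write_estpost_fixture(td, paste0("s", S), "alpha", list(m))
    write_estpost_fixture(td, paste0("s", S), "beta", list(m))
    for (burnin in unique(pmin(c(0, 1, S %/% 2, S - 1), S - 1))) {
      for (thin in c(1, 2, 3, 10)) {
        ps <- combine_bgc_output(td, burnin = burnin, thin = thin,
                                 prefix = paste0("s", S))
        expect_identical(nrow(ps$params$alpha$samples),
                         oracle_retained(S, burnin, thin),
                         info = sprintf("S=%d burnin=%d thin=%d",
                                        S, burnin, thin))
        # closed form agrees too
        expect_identical(nrow(ps$params$alpha$samples),
                         as.integer(ceiling((S - burnin) / thin)))
      }
    }
  }
})

test_that("a second combine pass with burnin 0, thin 1 is idempotent", {
  td <- withr::local_tempdir()
  m <- matrix(rnorm(200), nrow = 100, ncol = 2)
  write_estpost_fixture(td, "r", "alpha", list(m))
  write_estpost_fixture(td, "r", "beta", list(m))
  ps1 <- combine_bgc_output(td, burnin = 30, thin = 3, prefix = "r")
  td2 <- withr::local_tempdir()
  write_estpost_fixture(td2, "r2", "alpha", list(ps1$params$alpha$samples))
  write_estpost_fixture(td2, "r2", "beta", list(ps1$params$beta$samples))
  ps2 <- combine_bgc_output(td2, burnin = 0, thin = 1, prefix = "r2")
  expect_equal(ps2$params$alpha$samples, ps1$params$alpha$samples,
               tolerance = 1e-12)
})

test_that("trace_stats pins degenerate cases and recovers AR(1) autocorrelation", {
  td <- withr::local_tempdir()
  const <- matrix(rep(3.14, 50), ncol = 1)
  write_estpost_fixture(td, "c", "alpha", list(const))
  write_estpost_fixture(td, "c", "beta", list(const))
  ps <- combine_bgc_output(td, prefix = "c")
  s <- trace_stats(ps, "alpha", entity = 1)$summary
  expect_equal(s$variance, 0)
  expect_equal(s$lag1_autocorr, 0)

  # two replicates with means 0 and 10
  td2 <- withr::local_tempdir()
  write_estpost_fixture(td2, "m", "alpha",
                        list(matrix(0, 100, 1), matrix(10, 100, 1)))
  write_estpost_fixture(td2, "m", "beta",
                        list(matrix(0, 100, 1), matrix(10, 100, 1)))
  ps2 <- combine_bgc_output(td2, prefix = "m")
  s2 <- trace_stats(ps2, "alpha", entity = 1)$summary
  expect_equal(s2$mean, c(0, 10))

  # AR(1) with phi = 0.5 at n = 10000
  x <- withr::with_seed(123, clinekit:::ar1_series(10000, 0.5))
  td3 <- withr::local_tempdir()
  write_estpost_fixture(td3, "a", "alpha", list(matrix(x, ncol = 1)))
  write_estpost_fixture(td3, "a", "beta", list(matrix(x, ncol = 1)))
  ps3 <- combine_bgc_output(td3, prefix = "a")
  s3 <- trace_stats(ps3, "alpha", entity = 1)$summary
  expect_lt(abs(s3$lag1_autocorr - 0.5), 0.05)
})

test_that("posterior archives round-trip through write/read", {
  truth <- simulation_truth(n_loci = 5, draws_per_replicate = 100, seed = 9)
  td <- withr::local_tempdir()
  simulate_bgc_posterior(truth, td, prefix = "sim")
  ps <- combine_bgc_output(td, burnin = 10, thin = 2, prefix = "sim")
  td2 <- withr::local_tempdir()
  write_posterior(ps, td2)
  back <- read_posterior(td2)
  expect_equal(back$params$alpha$samples, ps$params$alpha$samples,
               tolerance = 1e-12)
  expect_identical(back$params$alpha$replicate, ps$params$alpha$replicate)
  expect_identical(back$burnin, ps$burnin)
})
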
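#' Read a per-sample environmental covariate table
#'
#' Reads a CSV with a `sample_id` column, optional `latitude`/`longitude`
#' columns, and one or more numeric covariate columns (e.g. values of
#' BioClim raster layers extracted at each sampling locality). Raster
#' extraction itself is upstream of this package; only the extracted table
#' is consumed.
#'
#' @param path Path to the CSV.
#' @return Data frame of class `env_table` with attribute `covariates`
#'   naming the covariate columns. Missing covariate cells are kept as
#'   `NA` with a warning.
#' @export
read_env_table <- function(path) {
  if (!file.exists(path)) abort("environment table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) abort("no sample_id column in %s", path)
  if (anyDuplicated(df$sample_id)) {
    abort("duplicate sample_id: %s", df$sample_id[duplicated(df$sample_id)][1])
  }
  covs <- setdiff(names(df), c("sample_id", "latitude", "longitude"))
  if (!length(covs)) abort("no covariate columns in %s", path)
  for (cv in covs) {
    raw <- df[[cv]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & raw != "NA" & is.na(val))
    if (length(bad)) {
      abort("non-numeric covariate value '%s' at row %d, column '%s'",
            raw[bad[1]], bad[1], cv)
    }
    if (anyNA(val)) {
      warn("%d missing value(s) in covariate '%s'", sum(is.na(val)), cv)
    }
    df[[cv]] <- val
  }
  attr(df, "covariates") <- covs
  class(df) <- c("env_table", class(df))
  df
}

#' Regress genomic clines and hybrid indices on an environmental covariate
#'
#' The environment-association step of the cline workflow: ordinary
#' least-squares regression of per-individual hybrid index on an
#' environmental covariate, and, per selected locus, a regression of
#' genotype class (0/1/2 copies of the population-1-associated allele) on
#' the covariate — linear by default, or logistic on the allele-copy
#' proportion. Each fit returns slope, intercept, Pearson r, the slope's
#' p-value, and 95% confidence-band points for plotting.
#'
#' @param env An `env_table` from [read_env_table()].
#' @param hybrid_index Named numeric vector of per-sample hybrid indices
#'   in \[0, 1\] (names are sample IDs; joined to `env` by id).
#' @param covariate Name of the covariate column to use.
#' @param gm Optional [genotype_matrix()] providing per-locus genotype
#'   classes for the per-locus panels.
#' @param loci Optional locus IDs of `gm` to fit (default: none).
#' @param family `"linear"` or `"logistic"` for the per-locus fits.
#' @param band_level Confidence level of the plotted band.
#' @param band_points Number of covariate grid points in the band table.
#' @return A list with `hybrid_fit` (one-row data frame), `locus_fits`
#'   (one row per locus), and `bands` (data frame of fitted values with
#'   lower/upper bounds per fit, for ribbon plotting).
#' @export
clines_x_environment <- function(env, hybrid_index, covariate, gm = NULL,
                                 loci = NULL,
                                 family = c("linear", "logistic"),
                                 band_level = 0.95, band_points = 100) {
  family <- match.arg(family)
  if (!covariate %in% names(env)) {
    abort("covariate '%s' not in environment table", covariate)
  }
  ids <- intersect(env$sample_id, names(hybrid_index))
  x <- env[[covariate]][match(ids, env$sample_id)]
  h <- unname(hybrid_index[ids])
  ok <- !is.na(x) & !is.na(h)
  x <- x[ok]; h <- h[ok]; ids <- ids[ok]
  if (length(x) < 3) {
    abort("need >= 3 samples with both covariate and hybrid index")
  }
  if (stats::var(x) == 0) {
    abort("covariate '%s' has zero variance", covariate)
  }

  fit_one <- function(y, x, label, fam) {
    grid <- seq(min(x), max(x), length.out = band_points)
    if (fam == "logistic") {
      m <- stats::glm(cbind(y, 2 - y) ~ x, family = stats::binomial())
      pr <- stats::predict(m, data.frame(x = grid), type = "link",
                           se.fit = TRUE)
      z <- stats::qnorm((1 + band_level) / 2)
      band <- data.frame(
        fit_id = label, covariate_value = grid,
        fit = stats::plogis(pr$fit),
        lower = stats::plogis(pr$fit - z * pr$se.fit),
        upper = stats::plogis(pr$fit + z * pr$se.fit)
      )
      co <- summary(m)$coefficients
      stats_row <- data.frame(
        fit = label, slope = co["x", 1], intercept = co["(Intercept)", 1],
        r = stats::cor(x, y), p = co["x", 4], n = length(x),
        family = fam, stringsAsFactors = FALSE
      )
    } else {
      m <- stats::lm(y ~ x)
      pr <- stats::predict(m, data.frame(x = grid), interval = "confidence",
                           level = band_level)
      band <- data.frame(
        fit_id = label, covariate_value = grid,
        fit = pr[, "fit"], lower = pr[, "lwr"], upper = pr[, "upr"]
      )
      co <- summary(m)$coefficients
      p <- if (nrow(co) > 1) co["x", 4] else NA_real_
      stats_row <- data.frame(
        fit = label, slope = stats::coef(m)[["x"]],
        intercept = stats::coef(m)[["(Intercept)"]],
        r = stats::cor(x, y), p = p, n = length(x),
        family = fam, stringsAsFactors = FALSE
      )
    }
    list(stats = stats_row, band = band)
  }

  hy <- fit_one(h, x, "hybrid_index", "linear")
  bands <- hy$band
  locus_fits <- NULL
  if (!is.null(gm) && length(loci)) {
    li <- match(loci, gm$locus_ids)
    if (anyNA(li)) {
      abort("locus not in genotype matrix: %s",
            paste(loci[is.na(li)], collapse = ", "))
    }
    gi <- match(ids, gm$sample_ids)
    if (anyNA(gi)) {
      abort("sample(s) missing from genotype matrix: %s",
            paste(ids[is.na(gi)], collapse = ", "))
    }
    rows <- lapply(seq_along(loci), function(k) {
      y <- gm$genotypes[gi, li[k]]
      keep <- !is.na(y)
      if (sum(keep) < 3) {
        warn("locus %s: fewer than 3 genotyped samples, skipped", loci[k])
        return(NULL)
      }
      fit_one(y[keep], x[keep], loci[k], family)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) {
      locus_fits <- do.call(rbind, lapply(rows, `[[`, "stats"))
      bands <- rbind(bands, do.call(rbind, lapply(rows, `[[`, "band")))
    }
  }
  list(hybrid_fit = hy$stats, locus_fits = locus_fits, bands = bands,
       covariate = covariate)
}
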
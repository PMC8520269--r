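#' Equal-tailed posterior credible interval
#'
#' Empirical quantiles at `(1 - level)/2` and `(1 + level)/2` using linear
#' interpolation between order statistics (the default type-7 quantile
#' rule). This rule makes intervals nest: raising `level` never shrinks
#' the interval, so outlier calls are monotone in the credibility level.
#'
#' @param samples Numeric vector of posterior draws (>= 2, all finite).
#' @param level Interval mass, in (0, 1).
#' @return Numeric vector `c(low, high)`.
#' @export
equal_tailed_interval <- function(samples, level = 0.95) {
  if (length(samples) < 2) abort("need at least 2 posterior draws")
  if (!all(is.finite(samples))) abort("non-finite posterior draws")
  if (level <= 0 || level >= 1) abort("level must be in (0, 1)")
  unname(stats::quantile(samples, probs = c((1 - level) / 2,
                                            (1 + level) / 2),
                         type = 7))
}

#' Highest-posterior-density interval
#'
#' Shortest interval containing `level` of the draws, computed over the
#' sorted sample. Offered as an alternative to [equal_tailed_interval()]
#' for skewed posteriors; the credible-interval outlier rule defaults to
#' equal-tailed.
#'
#' @inheritParams equal_tailed_interval
#' @return Numeric vector `c(low, high)`.
#' @export
hpd_interval <- function(samples, level = 0.95) {
  if (length(samples) < 2) abort("need at least 2 posterior draws")
  if (!all(is.finite(samples))) abort("non-finite posterior draws")
  x <- sort(samples)
  n <- length(x)
  k <- max(1L, ceiling(level * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Credible-interval outlier rule
#'
#' A locus is an outlier for a cline parameter when the posterior credible
#' interval excludes the neutral expectation of zero: significantly
#' positive (`outlier_pos`) when the lower bound is above 0, significantly
#' negative (`outlier_neg`) when the upper bound is below 0.
#'
#' @inheritParams equal_tailed_interval
#' @param method `"equal_tailed"` (default) or `"hpd"`.
#' @return One of `"outlier_pos"`, `"outlier_neg"`, `"not_outlier"`.
#' @export
ci_outlier_flag <- function(samples, level = 0.95,
                            method = c("equal_tailed", "hpd")) {
  method <- match.arg(method)
  ci <- if (method == "hpd") hpd_interval(samples, level)
        else equal_tailed_interval(samples, level)
  interval_flag(ci)
}

interval_flag <- function(ci) {
  if (ci[1] > 0) "outlier_pos"
  else if (ci[2] < 0) "outlier_neg"
  else "not_outlier"
}

#' Prior-quantile outlier rule
#'
#' bgc reports, per locus, the quantile of the point estimate within the
#' zero-mean Gaussian conditional prior (the gamma quantile for the cline
#' center alpha, the zeta quantile for the cline rate beta). A locus is an
#' outlier when that quantile falls in the tails of the prior: below
#' `(1 - n)/2` (`outlier_neg`) or above `(1 + n)/2` (`outlier_pos`), where
#' `n` is the credibility mass of the central region (e.g. 0.95). Loci
#' inside the central region are `not_outlier`.
#'
#' @param q_median Posterior median of the locus's prior-quantile
#'   parameter, in \[0, 1\].
#' @param n Central credibility mass, in (0, 1).
#' @return One of `"outlier_pos"`, `"outlier_neg"`, `"not_outlier"`.
#' @export
quantile_outlier_flag <- function(q_median, n = 0.95) {
  if (any(is.na(q_median)) || any(q_median < 0) || any(q_median > 1)) {
    abort("quantile medians must lie in [0, 1]")
  }
  if (n <= 0 || n >= 1) abort("n must be in (0, 1)")
  lo <- (1 - n) / 2
  hi <- (1 + n) / 2
  ifelse(q_median < lo, "outlier_neg",
         ifelse(q_median > hi, "outlier_pos", "not_outlier"))
}

#' Classify alpha/beta outlier loci from a combined posterior
#'
#' Applies one or both outlier-detection rules to every locus of a
#' combined bgc posterior, independently for the cline center (alpha) and
#' cline rate (beta):
#' \itemize{
#'   \item `ci`: the posterior credible interval excludes zero
#'     ([ci_outlier_flag()]);
#'   \item `quantile`: the posterior median of the locus's conditional
#'     prior quantile (gamma for alpha, zeta for beta) falls in the
#'     prior's tails ([quantile_outlier_flag()]).
#' }
#' The final per-parameter verdict combines the selected methods by OR
#' (`combine = "any"`) or AND (`combine = "all"`). Signs are tracked
#' throughout: a positive alpha outlier has excess parental-population-1
#' ancestry, a negative one a deficit; a positive beta outlier marks an
#' exceptionally steep ancestry transition, a negative one a wide cline.
#'
#' @param ps A `bgc_posterior` containing `alpha` and `beta` (and, for the
#'   quantile method, `gamma-quantile` and `zeta-quantile`).
#' @param level Credible-interval mass for the `ci` method.
#' @param n Central prior mass for the `quantile` method.
#' @param methods Character subset of `c("ci", "quantile")`.
#' @param combine `"any"` (OR) or `"all"` (AND).
#' @param locus_ids Optional locus names; defaults to `locus_<i>`.
#' @param ci_method Interval type for the `ci` rule (see
#'   [ci_outlier_flag()]).
#' @return A data frame of class `outlier_classification`, one row per
#'   locus: per-method flags, interval bounds, posterior medians,
#'   prior-quantile medians, combined `alpha_outlier`/`beta_outlier`
#'   verdicts, and `alpha_sign`/`beta_sign` (+1, -1, 0).
#' @export
classify_outliers <- function(ps, level = 0.95, n = 0.95,
                              methods = c("ci", "quantile"),
                              combine = c("any", "all"),
                              locus_ids = NULL,
                              ci_method = "equal_tailed") {
  stopifnot(inherits(ps, "bgc_posterior"))
  combine <- match.arg(combine)
  methods <- match.arg(methods, c("ci", "quantile"), several.ok = TRUE)
  for (p in c("alpha", "beta")) {
    if (!p %in% names(ps$params)) abort("posterior lacks parameter '%s'", p)
  }
  a <- ps$params$alpha$samples
  b <- ps$params$beta$samples
  if (ncol(a) != ncol(b)) {
    abort("alpha (%d loci) and beta (%d loci) entity counts differ",
          ncol(a), ncol(b))
  }
  n_loci <- ncol(a)
  if (n_loci == 0) {
    return(empty_outlier_classification())
  }
  if (is.null(locus_ids)) locus_ids <- paste0("locus_", seq_len(n_loci))

  need_q <- "quantile" %in% methods
  if (need_q) {
    for (p in c("gamma-quantile", "zeta-quantile")) {
      if (!p %in% names(ps$params)) {
        abort(paste("quantile method requested but posterior lacks '%s';",
                    "extract the gamma and zeta quantile estimates from",
                    "the bgc output"), p)
      }
    }
    gq <- apply(ps$params$`gamma-quantile`$samples, 2, stats::median)
    zq <- apply(ps$params$`zeta-quantile`$samples, 2, stats::median)
    gq <- pmin(pmax(gq, 0), 1)
    zq <- pmin(pmax(zq, 0), 1)
  } else {
    gq <- rep(NA_real_, n_loci)
    zq <- rep(NA_real_, n_loci)
  }

  a_ci <- apply(a, 2, equal_or_hpd, level = level, ci_method = ci_method)
  b_ci <- apply(b, 2, equal_or_hpd, level = level, ci_method = ci_method)
  out <- data.frame(
    locus = locus_ids,
    alpha_median = apply(a, 2, stats::median),
    beta_median = apply(b, 2, stats::median),
    alpha_low = a_ci[1, ], alpha_high = a_ci[2, ],
    beta_low = b_ci[1, ], beta_high = b_ci[2, ],
    alpha_ci = apply(a_ci, 2, interval_flag),
    beta_ci = apply(b_ci, 2, interval_flag),
    gamma_q_median = gq,
    zeta_q_median = zq,
    stringsAsFactors = FALSE
  )
  out$alpha_q <- if (need_q) quantile_outlier_flag(gq, n) else NA_character_
  out$beta_q <- if (need_q) quantile_outlier_flag(zq, n) else NA_character_

  combine_flags <- function(flags) {
    hits <- lapply(flags, function(f) f != "not_outlier")
    if (combine == "any") Reduce(`|`, hits) else Reduce(`&`, hits)
  }
  a_flags <- list()
  b_flags <- list()
  if ("ci" %in% methods) {
    a_flags$ci <- out$alpha_ci; b_flags$ci <- out$beta_ci
  }
  if (need_q) {
    a_flags$q <- out$alpha_q; b_flags$q <- out$beta_q
  }
  out$alpha_outlier <- combine_flags(a_flags)
  out$beta_outlier <- combine_flags(b_flags)
  out$alpha_sign <- ifelse(out$alpha_outlier, sign(out$alpha_median), 0)
  out$beta_sign <- ifelse(out$beta_outlier, sign(out$beta_median), 0)
  class(out) <- c("outlier_classification", class(out))
  out
}

equal_or_hpd <- function(x, level, ci_method) {
  if (ci_method == "hpd") hpd_interval(x, level)
  else equal_tailed_interval(x, level)
}

empty_outlier_classification <- function() {
  out <- data.frame(
    locus = character(0), alpha_median = numeric(0), beta_median = numeric(0),
    alpha_low = numeric(0), alpha_high = numeric(0),
    beta_low = numeric(0), beta_high = numeric(0),
    alpha_ci = character(0), beta_ci = character(0),
    gamma_q_median = numeric(0), zeta_q_median = numeric(0),
    alpha_q = character(0), beta_q = character(0),
    alpha_outlier = logical(0), beta_outlier = logical(0),
    alpha_sign = numeric(0), beta_sign = numeric(0),
    stringsAsFactors = FALSE
  )
  class(out) <- c("outlier_classification", class(out))
  out
}

#' Write an outlier classification table as TSV
#'
#' The table feeds the cline plotting and genome-mapping steps.
#'
#' @param oc An `outlier_classification` from [classify_outliers()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_outlier_table <- function(oc, path) {
  write_tsv(as.data.frame(oc), path)
}

#' Read an outlier classification table written by [write_outlier_table()]
#'
#' @param path Path to the TSV.
#' @return An `outlier_classification` data frame.
#' @export
read_outlier_table <- function(path) {
  out <- read_tsv(path)
  class(out) <- c("outlier_classification", class(out))
  out
}
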
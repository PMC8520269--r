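#' Genomic cline ancestry probability
#'
#' The polynomial genomic cline function of Gompert & Buerkle: the
#' probability that a gene copy at a locus derives from parental
#' population 1, given an individual's hybrid index `h` and the locus's
#' cline center (`alpha`) and rate (`beta`):
#' \deqn{\phi = h + 2h(1-h)\,[\alpha + \beta(2h - 1)]}
#' clamped to \[0, 1\]. With `alpha = beta = 0` the cline is neutral,
#' `phi = h`; `alpha` shifts ancestry probability up or down and `beta`
#' steepens (`beta > 0`) or widens (`beta < 0`) the transition. The
#' endpoints are pinned: `phi(0) = 0` and `phi(1) = 1` for any parameter
#' values, because `2h(1-h)` vanishes there.
#'
#' @param h Hybrid index, in \[0, 1\] (vectorized).
#' @param alpha Cline center parameter (vectorized).
#' @param beta Cline rate parameter (vectorized).
#' @param clamp Clamp the polynomial to \[0, 1\] (default `TRUE`); set
#'   `FALSE` to inspect the raw polynomial.
#' @return Numeric vector of ancestry probabilities.
#' @export
phi <- function(h, alpha = 0, beta = 0, clamp = TRUE) {
  if (any(is.na(h)) || any(h < 0) || any(h > 1)) {
    abort("hybrid index h must lie in [0, 1]")
  }
  val <- h + 2 * h * (1 - h) * (alpha + beta * (2 * h - 1))
  if (clamp) val <- pmin(pmax(val, 0), 1)
  val
}

#' Per-locus phi cline curves over a hybrid-index grid
#'
#' Evaluates each locus's genomic cline at its posterior-median `alpha`
#' and `beta` on a uniform hybrid-index grid, and summarizes each admixed
#' individual's hybrid index as its posterior median (for the marginal
#' histogram of the phi plot).
#'
#' @param ps A `bgc_posterior` containing `alpha`, `beta`, and (optional,
#'   for the histogram) `hi`.
#' @param oc Optional `outlier_classification` used to colour outlier
#'   curves; joined by position.
#' @param grid_size Number of grid points (>= 2); a grid of 101 gives
#'   steps of 0.01.
#' @return An object of class `cline_curves`: `locus_ids`, `h_grid`,
#'   `phi` (loci x grid matrix), `hybrid_index` (per-individual posterior
#'   medians, or `NULL`), `alpha`, `beta` (per-locus medians), and
#'   `outlier` flags.
#' @export
phi_curves <- function(ps, oc = NULL, grid_size = 101) {
  stopifnot(inherits(ps, "bgc_posterior"))
  if (grid_size < 2) abort("grid_size must be >= 2")
  for (p in c("alpha", "beta")) {
    if (!p %in% names(ps$params)) abort("posterior lacks parameter '%s'", p)
  }
  a_med <- apply(ps$params$alpha$samples, 2, stats::median)
  b_med <- apply(ps$params$beta$samples, 2, stats::median)
  n_loci <- length(a_med)
  locus_ids <- if (!is.null(oc) && nrow(oc) == n_loci) {
    oc$locus
  } else {
    paste0("locus_", seq_len(n_loci))
  }
  h_grid <- seq(0, 1, length.out = grid_size)
  phi_mat <- t(vapply(seq_len(n_loci),
                      function(i) phi(h_grid, a_med[i], b_med[i]),
                      numeric(grid_size)))
  hi <- if ("hi" %in% names(ps$params)) {
    apply(ps$params$hi$samples, 2, stats::median)
  }
  outlier <- if (!is.null(oc) && nrow(oc) == n_loci) {
    oc$alpha_outlier | oc$beta_outlier
  } else {
    rep(FALSE, n_loci)
  }
  structure(
    list(locus_ids = locus_ids, h_grid = h_grid, phi = phi_mat,
         hybrid_index = hi, alpha = a_med, beta = b_med, outlier = outlier),
    class = "cline_curves"
  )
}

#' Tidy a cline_curves object for export or plotting
#'
#' @param x A `cline_curves`.
#' @param ... Unused.
#' @return Long-format data frame: `locus`, `h`, `phi`, `outlier`.
#' @export
as.data.frame.cline_curves <- function(x, ...) {
  data.frame(
    locus = rep(x$locus_ids, each = length(x$h_grid)),
    h = rep(x$h_grid, times = length(x$locus_ids)),
    phi = as.vector(t(x$phi)),
    outlier = rep(x$outlier, each = length(x$h_grid)),
    stringsAsFactors = FALSE
  )
}

#' Alpha-beta outlier-space summary
#'
#' Summarizes the joint distribution of per-locus posterior-median cline
#' parameters: a 2-D kernel density estimate over the (alpha, beta)
#' medians (normal-reference bandwidth on a 100 x 100 grid), the per-locus
#' points themselves, and polygon hulls enclosing each outlier class
#' (alpha-positive, alpha-negative, beta-positive, beta-negative). Classes
#' with fewer than three loci yield no polygon (degenerate geometry) but
#' their points are still reported.
#'
#' @param oc An `outlier_classification` from [classify_outliers()].
#' @param hull_mode `"convex"` (default, deterministic) or `"concave"`
#'   (k-nearest-neighbour concave hull; falls back to convex when the
#'   concave construction fails to enclose all points).
#' @param concavity For concave mode, the starting number of neighbours
#'   `k` (>= 3); larger is smoother.
#' @param grid_n Density grid resolution per axis.
#' @return A list with `points` (data frame: locus, alpha, beta, class),
#'   `density` (list `x`, `y`, `z` from [MASS::kde2d()]), and `hulls`
#'   (named list of polygon data frames with columns `alpha`, `beta`).
#' @export
alpha_beta_summary <- function(oc, hull_mode = c("convex", "concave"),
                               concavity = 10, grid_n = 100) {
  hull_mode <- match.arg(hull_mode)
  if (!nrow(oc)) abort("no loci in the outlier classification")
  cls <- rep("none", nrow(oc))
  cls[oc$alpha_outlier & oc$alpha_sign > 0] <- "alpha_pos"
  cls[oc$alpha_outlier & oc$alpha_sign < 0] <- "alpha_neg"
  # a locus can be both an alpha and beta outlier; report beta class in
  # the dedicated beta columns
  beta_cls <- rep("none", nrow(oc))
  beta_cls[oc$beta_outlier & oc$beta_sign > 0] <- "beta_pos"
  beta_cls[oc$beta_outlier & oc$beta_sign < 0] <- "beta_neg"

  points <- data.frame(locus = oc$locus, alpha = oc$alpha_median,
                       beta = oc$beta_median, alpha_class = cls,
                       beta_class = beta_cls, stringsAsFactors = FALSE)

  dens <- if (nrow(oc) >= 2 &&
              stats::var(points$alpha) > 0 && stats::var(points$beta) > 0) {
    MASS::kde2d(points$alpha, points$beta, n = grid_n)
  }

  hulls <- list()
  for (klass in c("alpha_pos", "alpha_neg")) {
    hulls[[klass]] <- class_hull(points[points$alpha_class == klass, ],
                                 hull_mode, concavity)
  }
  for (klass in c("beta_pos", "beta_neg")) {
    hulls[[klass]] <- class_hull(points[points$beta_class == klass, ],
                                 hull_mode, concavity)
  }
  hulls <- hulls[!vapply(hulls, is.null, logical(1))]
  list(points = points, density = dens, hulls = hulls)
}

# Polygon hull around one outlier class; NULL when degenerate (< 3 loci).
class_hull <- function(pts, hull_mode, concavity) {
  if (nrow(pts) < 3) return(NULL)
  xy <- cbind(pts$alpha, pts$beta)
  idx <- if (hull_mode == "concave") {
    concave_hull_idx(xy, k = max(3L, as.integer(concavity)))
  } else {
    grDevices::chull(xy)
  }
  data.frame(alpha = xy[idx, 1], beta = xy[idx, 2])
}

# k-nearest-neighbour concave hull (Moreira & Santos style): walk the
# boundary choosing among the k nearest unvisited points the one with the
# largest right-hand turn, increasing k on failure; falls back to the
# convex hull when no simple enclosing polygon is found.
concave_hull_idx <- function(xy, k = 10) {
  n <- nrow(xy)
  if (n <= 3) return(grDevices::chull(xy))
  for (kk in seq(min(k, n - 1), n - 1)) {
    idx <- try_concave_walk(xy, kk)
    if (!is.null(idx) && all(points_in_poly(xy, xy[idx, , drop = FALSE]))) {
      return(idx)
    }
  }
  grDevices::chull(xy)
}

try_concave_walk <- function(xy, k) {
  n <- nrow(xy)
  start <- which.min(xy[, 2])
  hull <- start
  used <- rep(FALSE, n)
  cur <- start
  prev_angle <- 0
  for (step in seq_len(3 * n)) {
    if (step > 1 && cur == start) return(hull[-length(hull)])
    used[cur] <- TRUE
    d <- sqrt(colSums((t(xy) - xy[cur, ])^2))
    cand <- order(d)
    cand <- cand[cand != cur & (!used[cand] | cand == start)]
    # the start point only becomes eligible again after a few steps
    if (length(hull) < 3) cand <- cand[cand != start]
    cand <- utils::head(cand, k)
    if (!length(cand)) return(NULL)
    ang <- atan2(xy[cand, 2] - xy[cur, 2], xy[cand, 1] - xy[cur, 1])
    turn <- (prev_angle - ang) %% (2 * pi)
    ord <- order(turn, decreasing = TRUE)
    nxt <- NA_integer_
    for (ci in ord) {
      if (!segment_crosses(xy, hull, cur, cand[ci])) {
        nxt <- cand[ci]
        prev_angle <- atan2(xy[nxt, 2] - xy[cur, 2], xy[nxt, 1] - xy[cur, 1])
        break
      }
    }
    if (is.na(nxt)) return(NULL)
    hull <- c(hull, nxt)
    cur <- nxt
  }
  NULL
}

segment_crosses <- function(xy, hull, a, b) {
  if (length(hull) < 2) return(FALSE)
  p1 <- xy[a, ]; p2 <- xy[b, ]
  for (i in seq_len(length(hull) - 1)) {
    q1 <- xy[hull[i], ]; q2 <- xy[hull[i + 1], ]
    if (a %in% hull[c(i, i + 1)] || b %in% hull[c(i, i + 1)]) next
    if (segments_intersect(p1, p2, q1, q2)) return(TRUE)
  }
  FALSE
}

segments_intersect <- function(p1, p2, q1, q2) {
  o <- function(a, b, c) {
    v <- (b[2] - a[2]) * (c[1] - b[1]) - (b[1] - a[1]) * (c[2] - b[2])
    sign(v)
  }
  o1 <- o(p1, p2, q1); o2 <- o(p1, p2, q2)
  o3 <- o(q1, q2, p1); o4 <- o(q1, q2, p2)
  (o1 != o2) && (o3 != o4)
}

#' Test whether points fall inside or on a polygon
#'
#' Ray-casting point-in-polygon with an explicit on-boundary check, used
#' to verify hull containment.
#'
#' @param xy Two-column matrix of points.
#' @param poly Two-column matrix of polygon vertices (closed implicitly).
#' @return Logical vector, one per point.
#' @export
points_in_poly <- function(xy, poly) {
  xy <- as.matrix(xy); poly <- as.matrix(poly)
  n <- nrow(poly)
  eps <- 1e-9
  vapply(seq_len(nrow(xy)), function(i) {
    px <- xy[i, 1]; py <- xy[i, 2]
    inside <- FALSE
    j <- n
    for (v in seq_len(n)) {
      x1 <- poly[v, 1]; y1 <- poly[v, 2]
      x2 <- poly[j, 1]; y2 <- poly[j, 2]
      # on-segment check
      d <- abs((x2 - x1) * (py - y1) - (px - x1) * (y2 - y1))
      seg_len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
      if (seg_len > 0 && d / seg_len < eps &&
          px >= min(x1, x2) - eps && px <= max(x1, x2) + eps &&
          py >= min(y1, y2) - eps && py <= max(y1, y2) + eps) {
        return(TRUE)
      }
      if (seg_len == 0 && abs(px - x1) < eps && abs(py - y1) < eps) {
        return(TRUE)
      }
      if ((y1 > py) != (y2 > py) &&
          px < (x2 - x1) * (py - y1) / (y2 - y1) + x1) {
        inside <- !inside
      }
      j <- v
    }
    inside
  }, logical(1))
}
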
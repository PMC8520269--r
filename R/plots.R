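# All plotting functions return ggplot objects; rendering to files is a
# separate, thin step (save_figure) so tests and pipelines can assert on
# the underlying data rather than on pixels.

#' Plot MCMC traces per replicate
#'
#' Visual mixing/convergence check for a combined posterior: one line per
#' replicate of retained draws. Well-mixed replicates overlap and show no
#' trend.
#'
#' @param ps A `bgc_posterior`.
#' @param param Parameter to trace.
#' @param entity Entity column (see [trace_stats()]).
#' @return A ggplot object.
#' @export
plot_traces <- function(ps, param = "LnL", entity = NULL) {
  ts <- trace_stats(ps, param = param, entity = entity)
  df <- ts$trace
  df$replicate <- factor(df$replicate)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$draw, y = .data$value,
                                   colour = .data$replicate)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "retained draw", y = param,
                  title = sprintf("MCMC trace: %s", param)) +
    ggplot2::theme_minimal()
}

#' Phi cline plot with hybrid-index histogram
#'
#' The classic genomic-cline figure: per-locus ancestry-probability curves
#' phi(h) against hybrid index, outlier loci highlighted, with a marginal
#' histogram of the admixed individuals' posterior-median hybrid indices
#' above the cline panel.
#'
#' @param cc A `cline_curves` from [phi_curves()].
#' @return A patchwork-composed ggplot object.
#' @export
plot_phi <- function(cc) {
  stopifnot(inherits(cc, "cline_curves"))
  df <- as.data.frame(cc)
  main <- ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$phi,
                                           group = .data$locus)) +
    ggplot2::geom_line(data = df[!df$outlier, ],
                       colour = "grey60", alpha = 0.5, linewidth = 0.3) +
    ggplot2::geom_line(data = df[df$outlier, ],
                       colour = "firebrick", linewidth = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "black") +
    ggplot2::labs(x = "hybrid index (h)",
                  y = expression(phi ~ "(prob. population-1 ancestry)")) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  if (is.null(cc$hybrid_index)) return(main)
  hist_df <- data.frame(h = cc$hybrid_index)
  top <- ggplot2::ggplot(hist_df, ggplot2::aes(x = .data$h)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey40",
                            boundary = 0, closed = "left") +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "count") +
    ggplot2::theme_minimal()
  patchwork::wrap_plots(top, main, ncol = 1, heights = c(1, 3))
}

#' Alpha-beta outlier-space plot
#'
#' 2-D density contours of per-locus posterior-median (alpha, beta) with
#' the loci as points, coloured by outlier class, and polygon hulls around
#' each outlier class.
#'
#' @param abs_ An alpha-beta summary from [alpha_beta_summary()].
#' @return A ggplot object.
#' @export
plot_alpha_beta <- function(abs_) {
  pts <- abs_$points
  pts$class <- ifelse(pts$alpha_class != "none", pts$alpha_class,
                      pts$beta_class)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$alpha, y = .data$beta))
  if (!is.null(abs_$density)) {
    d <- abs_$density
    dens_df <- data.frame(alpha = rep(d$x, times = length(d$y)),
                          beta = rep(d$y, each = length(d$x)),
                          z = as.vector(d$z))
    p <- p + ggplot2::geom_contour(data = dens_df,
                                   ggplot2::aes(z = .data$z),
                                   colour = "grey70", bins = 8)
  }
  p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$class), size = 1)
  for (nm in names(abs_$hulls)) {
    hull <- abs_$hulls[[nm]]
    hull$class <- nm
    p <- p + ggplot2::geom_polygon(data = hull,
                                   ggplot2::aes(fill = .data$class),
                                   alpha = 0.15, colour = "grey30")
  }
  p + ggplot2::labs(x = expression(alpha ~ "(cline center)"),
                    y = expression(beta ~ "(cline rate)")) +
    ggplot2::theme_minimal()
}

#' Dual ideogram of cline parameters along chromosomes
#'
#' Schematic karyotype with each chromosome drawn twice: heatmap bands of
#' the alpha values on the left copy and of beta on the right, wider bands
#' marking SNPs inside known genes.
#'
#' @param alpha_bands,beta_bands Band tables from [ideogram_bands()].
#' @param karyotype Data frame: `chromosome`, `length`.
#' @return A ggplot object.
#' @export
plot_outlier_ideogram <- function(alpha_bands, beta_bands, karyotype) {
  karyotype$xpos <- seq_len(nrow(karyotype))
  frame <- rbind(
    transform(karyotype, x = xpos - 0.32, param = "alpha"),
    transform(karyotype, x = xpos + 0.08, param = "beta")
  )
  band_rects <- function(bands, param) {
    if (!nrow(bands)) return(NULL)
    x <- frame$x[match(paste(bands$chromosome, param),
                       paste(frame$chromosome, frame$param))]
    data.frame(xmin = x, xmax = x + 0.24,
               ymin = bands$band_start, ymax = bands$band_end,
               value = bands$value, param = param)
  }
  rects <- rbind(band_rects(alpha_bands, "alpha"),
                 band_rects(beta_bands, "beta"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(data = frame,
                       ggplot2::aes(xmin = .data$x, xmax = .data$x + 0.24,
                                    ymin = 1, ymax = .data$length),
                       fill = NA, colour = "grey30", linewidth = 0.3)
  if (!is.null(rects) && nrow(rects)) {
    p <- p + ggplot2::geom_rect(
      data = rects,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax,
                   fill = .data$value)) +
      ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                    high = "firebrick", midpoint = 0)
  }
  p + ggplot2::scale_x_continuous(breaks = karyotype$xpos,
                                  labels = karyotype$chromosome) +
    ggplot2::labs(x = NULL, y = "position (bp)",
                  fill = "cline\nparameter") +
    ggplot2::theme_minimal()
}

#' Cline-versus-environment regression plot
#'
#' Fitted regression lines of hybrid index (and optionally per-locus
#' genotype class) on an environmental covariate, with shaded confidence
#' bands.
#'
#' @param assoc Result of [clines_x_environment()].
#' @return A ggplot object.
#' @export
plot_clines_env <- function(assoc) {
  bands <- assoc$bands
  ggplot2::ggplot(bands, ggplot2::aes(x = .data$covariate_value,
                                      y = .data$fit,
                                      group = .data$fit_id)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "grey70", alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$fit_id)) +
    ggplot2::labs(x = assoc$covariate, y = "fitted value",
                  colour = "fit") +
    ggplot2::theme_minimal()
}

#' Save a figure headlessly
#'
#' Renders a ggplot (or patchwork) to PNG or SVG via the cairo devices.
#'
#' @param plot The plot object.
#' @param path Output path; the extension selects the device (`.png` or
#'   `.svg`).
#' @param width,height Size in inches.
#' @param dpi Resolution for raster output.
#' @return The path, invisibly.
#' @export
save_figure <- function(plot, path, width = 7, height = 5, dpi = 150) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = grDevices::png(path, width = width, height = height,
                         units = "in", res = dpi, type = "cairo"),
    svg = grDevices::svg(path, width = width, height = height),
    abort("unsupported figure format '%s' (use .png or .svg)", ext)
  )
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}
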
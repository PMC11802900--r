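#' Plot bootstrapped color distances with confidence intervals
#'
#' Open points are replicate-distribution means, bars the percentile
#' interval, with the discrimination threshold as a dotted line.
#'
#' @param object A [bootcoldist()] result, or the `jnd` table of
#'   [run_full_analysis()] (facetted by visual system when a `system` column
#'   is present).
#' @param threshold JND threshold line (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot boot_coldist
#' @export
autoplot.boot_coldist <- function(object, threshold = 1, ...) {
  df <- as_tibble(object)
  if (!"comparison" %in% names(df)) df$comparison <- "a vs b"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison,
                                        y = .data$mean_jnd,
                                        color = .data$channel)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             shape = 1,
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(y = "color distance (JND)", x = NULL, color = NULL) +
    ggplot2::theme_minimal()
  if ("system" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$system))
  }
  p
}

#' Plot stimuli in a visual system's chromaticity space
#'
#' Trichromatic systems plot as the Maxwell triangle; tetrachromatic systems
#' are shown as the (x, y) projection of the tetrahedron (the z axis carries
#' the UV/violet direction). Vertices are labelled with receptor names.
#'
#' @param coords A [chromaticity_coords()] table (a `group` column, if
#'   present, colors the points).
#' @param vs The `visual_system` used.
#' @return A ggplot object.
#' @export
plot_colspace <- function(coords, vs) {
  stopifnot(inherits(vs, "visual_system"))
  V <- simplex_vertices(nrow(vs$receptors))
  verts <- tibble(receptor = vs$receptors$receptor,
                  x = V[, 1], y = V[, 2])
  aes_pt <- if ("group" %in% names(coords)) {
    ggplot2::aes(x = .data$x, y = .data$y, color = .data$group)
  } else {
    ggplot2::aes(x = .data$x, y = .data$y)
  }
  ggplot2::ggplot(coords, aes_pt) +
    ggplot2::geom_polygon(data = verts,
                          ggplot2::aes(x = .data$x, y = .data$y),
                          inherit.aes = FALSE, fill = NA, color = "grey40") +
    ggplot2::geom_text(data = verts,
                       ggplot2::aes(x = .data$x * 1.12, y = .data$y * 1.12,
                                    label = .data$receptor),
                       inherit.aes = FALSE, size = 3) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = vs$name, color = NULL)
}

#' Plot group mean reflectance with standard-deviation ribbons
#'
#' @param agg An [aggregate_spectra()] result with one grouping column.
#' @return A ggplot object.
#' @export
plot_spectra <- function(agg) {
  key <- setdiff(names(agg), c("wavelength", "mean", "sd"))[1]
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$wavelength, y = .data$mean,
                                    color = .data[[key]],
                                    fill = .data[[key]])) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance") +
    ggplot2::theme_minimal()
}
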
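# Base-graphics views of the descriptors: polar sphere-projection plot
# (phi as radius, theta as circumference), smoothed histograms, and the
# PCA landscape.

#' Polar plot of sphere projections
#'
#' Plots projection tables from [dual_projection()] as a polar diagram with
#' the polar angle phi as radius and the azimuth theta as circumference.
#'
#' @param projections data frame with columns theta_vh, phi_vh, theta_vl,
#'   phi_vl (degrees).
#' @param max_phi radial limit in degrees (default 90).
#' @param col_vh,col_vl point colors for the two domains.
#' @param ... passed to [graphics::points()].
#' @return invisibly, the plotted xy coordinates.
#' @export
plot_sphere_projection <- function(projections, max_phi = 90,
                                   col_vh = "red", col_vl = "orange", ...) {
  graphics::plot(NA, xlim = c(-max_phi, max_phi), ylim = c(-max_phi, max_phi),
                 asp = 1, xlab = "", ylab = "", axes = FALSE)
  for (r in pretty(c(0, max_phi))) {
    th <- seq(0, 2 * pi, length.out = 181)
    graphics::lines(r * cos(th), r * sin(th), col = "grey80")
  }
  pts <- function(theta, phi, col) {
    t <- deg2rad(theta)
    graphics::points(phi * cos(t), phi * sin(t), col = col, pch = 16,
                     cex = 0.5, ...)
    cbind(phi * cos(t), phi * sin(t))
  }
  xy_vh <- pts(projections$theta_vh, projections$phi_vh, col_vh)
  xy_vl <- pts(projections$theta_vl, projections$phi_vl, col_vl)
  graphics::legend("topright", legend = c("V_H", "V_L"), bty = "n",
                   col = c(col_vh, col_vl), pch = 16)
  invisible(list(vh = xy_vh, vl = xy_vl))
}

#' Plot a smoothed histogram curve
#'
#' @param sh a \code{SmoothedHistogram}.
#' @param add overlay on an existing plot.
#' @param ... passed to [graphics::lines()] / [graphics::plot()].
#' @export
plot_smoothed_histogram <- function(sh, add = FALSE, ...) {
  if (add) graphics::lines(sh$centers, sh$density, ...)
  else graphics::plot(sh$centers, sh$density, type = "l",
                      xlab = "value", ylab = "density", ...)
  invisible(sh)
}

#' Image plot of a torsion PCA landscape
#'
#' @param land a \code{PcaLandscape}.
#' @param ... passed to [graphics::image()].
#' @export
plot_landscape <- function(land, ...) {
  graphics::image(land$x, land$y, land$surface,
                  xlab = "PC1", ylab = "PC2",
                  main = land$name,
                  col = grDevices::hcl.colors(30, "viridis", rev = TRUE), ...)
  invisible(land)
}
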
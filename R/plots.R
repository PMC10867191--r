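#' Plot flower loci in the bee colour hexagon
#'
#' Draws the hexagon outline (vertices at the pure-receptor directions),
#' the achromatic disc around the centre, and one point per species,
#' optionally coloured by the approximate human colour of its spectrum.
#'
#' @param signals data.frame from [spectrum_to_signals] (needs `x`, `y`).
#' @param achromatic_radius radius of the achromatic disc to draw.
#' @param col point colours (e.g. from [spec_to_rgb]); recycled.
#' @param main plot title.
#' @export
plot_hexagon <- function(signals, achromatic_radius = 0.11,
                         col = "grey30", main = "bee colour hexagon") {
  ang <- pi / 6 + (0:5) * pi / 3   # vertex directions
  vx <- cos(ang); vy <- sin(ang)
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 xlab = "x", ylab = "y", main = main, axes = FALSE)
  graphics::polygon(vx, vy, border = "grey60")
  th <- seq(0, 2 * pi, length.out = 120)
  graphics::lines(achromatic_radius * cos(th), achromatic_radius * sin(th),
                  col = "red")
  graphics::points(signals$x, signals$y, pch = 19, cex = 0.6, col = col)
  graphics::text(1.08 * vx, 1.08 * vy,
                 c("B-G", "B", "UV-B", "UV", "UV-G", "G")[c(1, 2, 3, 4, 5, 6)],
                 cex = 0.7, col = "grey40")
  invisible(signals)
}

#' Flower size by elevational zone
#'
#' Boxplot of flower diameter per zone on a log scale.
#'
#' @param records data.frame with `zone` and `size_mm`.
#' @export
plot_size_by_zone <- function(records) {
  graphics::boxplot(size_mm ~ zone, data = records, log = "y",
                    xlab = "", ylab = "flower size (mm)", las = 2)
  invisible(records)
}
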
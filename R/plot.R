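# Heatmap rendering of spatiotemporal maps, following the figure
# convention of overlaying the widefield diffraction limit and the
# extended SIM pass-band limit as dashed horizontal lines.

#' Plot a spatiotemporal map as a heatmap
#'
#' Periods (or temporal frequencies) on the x axis, spatial-frequency
#' radius on the y axis.  The widefield cutoff and the extended SIM limit
#' are overlaid as white and black dashed horizontal lines when the map
#' carries its configuration.
#'
#' @param x A `spatiotemporal_map`.
#' @param main Plot title; defaults to a metric/scheme label.
#' @param zlim Color range; defaults to the finite data range.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.spatiotemporal_map <- function(x, main = NULL, zlim = NULL, ...) {
  z <- t(x$matrix)  # image(): rows along x axis
  if (is.null(zlim)) {
    zlim <- range(z, finite = TRUE)
    if (!all(is.finite(zlim))) zlim <- c(0, 1)
  }
  main <- main %||% sprintf("%s (%s)", x$metric, x$scheme)
  graphics::image(
    x = seq_along(x$periods), y = x$radii, z = z, zlim = zlim,
    col = grDevices::hcl.colors(64, "viridis"),
    xlab = "modulation period index", ylab = "spatial frequency (px)",
    main = main, useRaster = TRUE, ...)
  graphics::axis(3, at = seq_along(x$periods), labels = x$periods,
                 cex.axis = 0.6, tick = FALSE, line = -1)
  if (!is.null(x$meta)) {
    cut <- x$meta$cutoff
    lim <- sim_passband_limit(cut, x$meta$fringe_period, x$meta$size)
    graphics::abline(h = cut, lty = 2, col = "white", lwd = 2)
    graphics::abline(h = lim, lty = 2, col = "black", lwd = 2)
  }
  invisible(x)
}

save_map_png <- function(map, path, width = 900, height = 700, ...) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  plot(map, ...)
  invisible(path)
}
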
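# Minimal field rendering: hex fields resampled to Cartesian rasters.

#' Plot a concentration field as a heat map
#'
#' Resamples the hexagonal field onto a Cartesian raster and draws it with
#' \code{image()}; the rest-state level sits mid-scale so deviations above
#' and below basal are visually symmetric, with the front-back interface at
#' the colour midpoint.
#'
#' @param sim simulation state.
#' @param species field name (default active Cdc42).
#' @param factor resampling factor.
#' @param ... passed to \code{image()}.
#' @return Invisibly, the raster list (x, y, z).
#' @export
plot_field <- function(sim, species = "cdc42_a", factor = 2, ...) {
  cz <- .hex_to_cart(sim$grid, get_field(sim, species), sim$mask, factor)
  bas <- basal_levels(sim$p)[[species]]
  lim <- max(abs(range(cz$z, na.rm = TRUE) - bas))
  graphics::image(cz$x, cz$y, cz$z, asp = 1, zlim = bas + c(-lim, lim),
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  xlab = "x (um)", ylab = "y (um)", main = species, ...)
  invisible(cz)
}

#' Orientation colour-wheel summary of the actin fields
#'
#' Returns, per site, the total filament density and the mean orientation
#' (circular mean over the six classes), the standard colour-wheel encoding
#' of cytoskeletal anisotropy.
#'
#' @param sim simulation state.
#' @return Data frame with \code{site}, \code{density}, \code{angle}
#'   (radians) and \code{coherence} (resultant length in [0, 1]).
#' @export
actin_orientation_summary <- function(sim) {
  ang <- (0:5) * pi / 3
  Ftot <- rowSums(sim$F)
  cx <- as.numeric(sim$F %*% cos(ang))
  cy <- as.numeric(sim$F %*% sin(ang))
  data.frame(site = seq_len(sim$grid$n), density = Ftot,
             angle = atan2(cy, cx),
             coherence = ifelse(Ftot > 0, sqrt(cx^2 + cy^2) / Ftot, 0))
}
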
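#' Quick-look map of a gridded result layer
#'
#' Basic image plot of one field of a `suitability_result` (or of the
#' elevation of a [climate_grid()]). Intended as a quick diagnostic, not a
#' cartographic product.
#'
#' @param result a `suitability_result` data frame.
#' @param field column to plot; default `"ei"`.
#' @param ... passed on to [graphics::image()].
#' @return Invisibly, the plotted matrix.
#' @export
plot_layer <- function(result, field = "ei", ...) {
  if (!field %in% names(result)) stop("no such field: ", field)
  lon <- sort(unique(result$lon))
  lat <- sort(unique(result$lat))
  z <- matrix(NA_real_, length(lon), length(lat))
  z[cbind(match(result$lon, lon), match(result$lat, lat))] <- result[[field]]
  graphics::image(lon, lat, z, xlab = "longitude", ylab = "latitude",
                  main = field, col = grDevices::hcl.colors(24, "viridis"),
                  useRaster = TRUE, ...)
  invisible(z)
}
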
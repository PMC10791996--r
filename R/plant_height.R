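#' Plant height from a DSM pair
#'
#' Canopy height model by surface differencing: the digital surface model
#' at the bare-soil date (`dsm0`) is the terrain baseline, the jointing-date
#' model (`dsm1`) includes the canopy, and plant height is their difference
#' converted to centimeters. Negative differences (terrain/DSM noise) are
#' clipped to zero; nodata propagates.
#'
#' @param dsm0 bare-soil `wl_raster`, elevations in meters.
#' @param dsm1 jointing-date `wl_raster`, elevations in meters.
#' @return a `wl_raster` of plant height in cm.
#' @export
compute_ph <- function(dsm0, dsm1) {
  if (!same_grid(dsm0, dsm1)) stop("DSM grids do not match")
  raster_like(dsm0, pmax((dsm1$values - dsm0$values) * 100, 0))
}

#' Plant height at sample points
#'
#' Mean canopy height within `radius` meters of each point (default 0.5 m,
#' the field protocol of averaging plants within a 50 cm circle).
#'
#' @param ph plant-height `wl_raster` (cm), e.g. from [compute_ph()].
#' @param points data frame with `x`, `y` (and optionally `id`) columns.
#' @param radius extraction radius in meters.
#' @return numeric vector of plant heights (cm).
#' @export
ph_at_points <- function(ph, points, radius = 0.5) {
  extract_at_points(ph, points, radius = radius)
}
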
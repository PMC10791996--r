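#' @title Vegetation indices for 4-band UAV imagery
#' @description
#' Closed-form spectral indices over the green (550 nm), red (660 nm),
#' red-edge (735 nm) and NIR (790 nm) reflectance bands. The 17 modelling
#' indices span greenness (RVI, DVI, NDVI, GNDVI, EVI2, CLgreen), structure
#' (MSR, MSAVI, GOSAVI, REOSAVI, RERDVI) and chlorophyll (CLre, CARI, NGRDI,
#' TVI, MTVI2, MTCI) groups; OSAVI is registered additionally as a
#' mask-support index. Where a printed formula flattens a radical or
#' fraction ambiguously, the standard literature form is used: MSR divides
#' by sqrt(NIR/R + 1); MSAVI and MTVI2 carry their square roots; REOSAVI
#' uses the red-edge band in the 1.16/(.. + 0.16) OSAVI pattern.
#' @name vegetation-indices
NULL

# each formula takes numeric vectors/matrices G, R, RE, NIR and returns the
# index; division by zero and negative radicands yield NA downstream
vi_formulas <- list(
  RVI     = function(G, R, RE, NIR) NIR / R,
  DVI     = function(G, R, RE, NIR) NIR - R,
  NDVI    = function(G, R, RE, NIR) (NIR - R) / (NIR + R),
  GNDVI   = function(G, R, RE, NIR) (NIR - G) / (NIR + G),
  EVI2    = function(G, R, RE, NIR) 2.5 * (NIR - R) / (NIR + 2.4 * R + 1),
  CLgreen = function(G, R, RE, NIR) NIR / G - 1,
  MSR     = function(G, R, RE, NIR) (NIR / R - 1) / sqrt(NIR / R + 1),
  MSAVI   = function(G, R, RE, NIR) {
    0.5 * ((2 * NIR + 1) - sqrt((2 * NIR + 1)^2 - 8 * (NIR - R)))
  },
  GOSAVI  = function(G, R, RE, NIR) 1.16 * (NIR - G) / (NIR + G + 0.16),
  REOSAVI = function(G, R, RE, NIR) 1.16 * (NIR - RE) / (NIR + RE + 0.16),
  RERDVI  = function(G, R, RE, NIR) (NIR - RE) / (NIR + RE),
  CLre    = function(G, R, RE, NIR) NIR / RE - 1,
  CARI    = function(G, R, RE, NIR) (RE - R) - 0.2 * (RE + R),
  NGRDI   = function(G, R, RE, NIR) (G - R) / (G + R),
  TVI     = function(G, R, RE, NIR) 60 * (NIR - G) - 100 * (R - G),
  MTVI2   = function(G, R, RE, NIR) {
    1.5 * (1.2 * (NIR - G) - 2.5 * (R - G)) /
      sqrt((2 * NIR + 1)^2 - (6 * NIR - 5 * sqrt(R)) - 0.5)
  },
  MTCI    = function(G, R, RE, NIR) (NIR - RE) / (RE - R),
  OSAVI   = function(G, R, RE, NIR) 1.16 * (NIR - R) / (NIR + R + 0.16)
)

#' Names of the modelling vegetation indices
#'
#' The 17 indices used as LAI predictors. `OSAVI` (used together with NDVI,
#' EVI2 and REOSAVI for wheat-pixel masking) is registered but not listed.
#'
#' @return character vector of length 17.
#' @export
vi_names <- function() setdiff(names(vi_formulas), "OSAVI")

#' Evaluate a vegetation index on numeric band values
#'
#' Vectorized evaluation of a registered index on reflectance values (e.g.
#' band values already extracted at sample points). Non-finite results
#' (zero denominators, negative radicands) become `NA`.
#'
#' @param name registered index name (see [vi_names()]; `OSAVI` also valid).
#' @param G,R,RE,NIR numeric vectors or matrices of reflectance.
#' @return numeric vector/matrix of index values.
#' @export
vi_values <- function(name, G, R, RE, NIR) {
  f <- vi_formulas[[name]]
  if (is.null(f)) {
    stop("unknown vegetation index '", name, "'; registered: ",
         paste(names(vi_formulas), collapse = ", "))
  }
  out <- suppressWarnings(f(G, R, RE, NIR))
  out[!is.finite(out)] <- NA_real_
  out
}

check_band_set <- function(bands) {
  stopifnot(is.list(bands), all(c("G", "R", "RE", "NIR") %in% names(bands)))
  for (b in c("R", "RE", "NIR")) {
    if (!same_grid(bands$G, bands[[b]])) stop("bands do not share a grid")
  }
  invisible(bands)
}

#' Compute a vegetation index raster
#'
#' @param bands named list of `wl_raster` bands `G, R, RE, NIR` on a shared
#'   grid.
#' @param name registered index name.
#' @return a `wl_raster`; nodata in any input band propagates, and singular
#'   pixels (zero denominator, negative radicand) are nodata.
#' @export
compute_vi <- function(bands, name) {
  check_band_set(bands)
  vals <- vi_values(name, bands$G$values, bands$R$values,
                    bands$RE$values, bands$NIR$values)
  # a nodata pixel in any input band is nodata in every index
  vals[is.na(bands$G$values) | is.na(bands$R$values) |
         is.na(bands$RE$values) | is.na(bands$NIR$values)] <- NA_real_
  raster_like(bands$G, vals)
}

#' Compute all 17 modelling vegetation indices
#'
#' @param bands named list of `wl_raster` bands `G, R, RE, NIR`.
#' @return named list of 17 `wl_raster` objects in stable order.
#' @export
compute_all_vi <- function(bands) {
  check_band_set(bands)
  out <- lapply(vi_names(), function(nm) compute_vi(bands, nm))
  names(out) <- vi_names()
  out
}
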
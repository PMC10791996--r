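#' Configuration for a synthetic UAV wheat scene
#'
#' Defines the statistical structure of a simulated jointing-stage winter
#' wheat field as seen by a 4-band UAV multispectral sensor (green 550 nm,
#' red 660 nm, red edge 735 nm, NIR 790 nm) at 0.1 m ground resolution,
#' together with the two digital surface models (bare soil and jointing
#' date) needed for plant-height extraction.
#'
#' The LAI field is a smooth Gaussian random field whose pointwise
#' distribution is mapped to a truncated normal with the configured mean,
#' SD and range. Plant height (cm) is linearly and positively related to
#' LAI. Canopy cover follows Beer-Lambert, `f = 1 - exp(-k * LAI)`, and
#' per-band reflectance is the cover-weighted mixture of canopy and soil
#' spectra, which reproduces the saturation of vegetation indices in dense
#' canopies. A periodic pattern with the sowing row spacing modulates
#' reflectance on wheat pixels.
#'
#' @param width,height scene size in pixels.
#' @param resolution ground sampling distance (m/pixel).
#' @param seed integer RNG seed; identical seeds give bit-identical scenes.
#' @param lai_range attainable LAI range (m2/m2).
#' @param lai_mean_sd target mean and SD of the LAI distribution.
#' @param ph_slope plant height gain (cm per LAI unit).
#' @param ph_intercept plant height at LAI 0 (cm).
#' @param ph_noise_sd SD of plant-height noise around the linear rule (cm).
#' @param extinction_k Beer-Lambert canopy extinction coefficient.
#' @param band_k_scale per-band multipliers on `extinction_k` (G, R, RE,
#'   NIR). Light extinction in a canopy is strongest where leaves absorb
#'   (red), weaker in the red edge and weakest in the scattering-dominated
#'   NIR, so each band saturates at a different rate; this is what makes
#'   red-edge ratio indices (MTCI, CLre) respond to LAI after the visible
#'   bands have saturated.
#' @param veg_reflectance,soil_reflectance length-4 reflectance vectors
#'   (G, R, RE, NIR), each in `[0, 1]`.
#' @param row_spacing sowing row spacing (m).
#' @param row_amplitude relative reflectance modulation of the row pattern.
#' @param noise_sd SD of additive reflectance noise.
#' @param dsm_noise_sd SD of elevation noise on the jointing-date DSM (m).
#' @param soil_strip_every,soil_strip_width spacing and width (pixels) of the
#'   bare-soil strips (paths/margins) that give the masking stage both classes.
#' @param n_points default number of ground sample points.
#' @param lai_noise_sd SD of LAI measurement noise at sample points (m2/m2).
#' @param ph_meas_noise_sd SD of tape-measured PH noise at sample points (cm).
#' @return a list of class `scene_config`.
#' @export
scene_config <- function(width = 256, height = 256, resolution = 0.1,
                         seed = 42L,
                         lai_range = c(0.61, 8.57),
                         lai_mean_sd = c(3.89, 1.93),
                         ph_slope = 5, ph_intercept = 20, ph_noise_sd = 2,
                         extinction_k = 0.5,
                         band_k_scale = c(G = 1.2, R = 1.8, RE = 0.9, NIR = 0.7),
                         veg_reflectance = c(G = 0.08, R = 0.05, RE = 0.30, NIR = 0.50),
                         soil_reflectance = c(G = 0.10, R = 0.16, RE = 0.20, NIR = 0.24),
                         row_spacing = 0.15, row_amplitude = 0.03,
                         noise_sd = 0.005, dsm_noise_sd = 0.01,
                         soil_strip_every = 64, soil_strip_width = 8,
                         n_points = 79,
                         lai_noise_sd = 0.15, ph_meas_noise_sd = 2) {
  cfg <- list(
    width = as.integer(width), height = as.integer(height),
    resolution = resolution, seed = as.integer(seed),
    lai_range = as.numeric(lai_range), lai_mean_sd = as.numeric(lai_mean_sd),
    ph_slope = ph_slope, ph_intercept = ph_intercept, ph_noise_sd = ph_noise_sd,
    extinction_k = extinction_k, band_k_scale = band_k_scale,
    veg_reflectance = veg_reflectance, soil_reflectance = soil_reflectance,
    row_spacing = row_spacing, row_amplitude = row_amplitude,
    noise_sd = noise_sd, dsm_noise_sd = dsm_noise_sd,
    soil_strip_every = as.integer(soil_strip_every),
    soil_strip_width = as.integer(soil_strip_width),
    n_points = as.integer(n_points),
    lai_noise_sd = lai_noise_sd, ph_meas_noise_sd = ph_meas_noise_sd
  )
  num <- unlist(cfg[c("resolution", "lai_range", "lai_mean_sd", "ph_slope",
                      "ph_intercept", "ph_noise_sd", "extinction_k",
                      "band_k_scale", "veg_reflectance", "soil_reflectance",
                      "row_spacing", "row_amplitude", "noise_sd",
                      "dsm_noise_sd")])
  if (any(!is.finite(num))) stop("scene_config: non-finite numeric field")
  if (cfg$lai_range[1] > cfg$lai_range[2]) stop("lai_range: min must be <= max")
  if (any(cfg$veg_reflectance < 0 | cfg$veg_reflectance > 1) ||
      any(cfg$soil_reflectance < 0 | cfg$soil_reflectance > 1)) {
    stop("reflectances must lie in [0, 1]")
  }
  if (cfg$resolution <= 0) stop("resolution must be > 0")
  if (cfg$n_points < 4) stop("n_points must be >= 4")
  if (length(cfg$veg_reflectance) != 4 || length(cfg$soil_reflectance) != 4) {
    stop("reflectance vectors must have 4 entries (G, R, RE, NIR)")
  }
  class(cfg) <- "scene_config"
  cfg
}

# smooth Gaussian random field via FFT filtering of white noise (periodic
# boundary; adequate for a synthetic stand-in)
gaussian_random_field <- function(nr, nc, sigma_px) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  fx <- c(0:(floor(nc / 2)), -((ceiling(nc / 2) - 1):1)) / nc
  fy <- c(0:(floor(nr / 2)), -((ceiling(nr / 2) - 1):1)) / nr
  gk <- exp(-2 * pi^2 * sigma_px^2 * outer(fy^2, fx^2, `+`))
  sm <- Re(stats::fft(stats::fft(z) * gk, inverse = TRUE)) / (nr * nc)
  sm
}

#' Generate a synthetic UAV scene bundle
#'
#' Produces co-registered rasters (4-band reflectance, truth LAI, truth
#' plant height, wheat mask, DSM pair) and a ground-sample table drawn with
#' [sample_ground_truth()]. All randomness is governed by `config$seed`.
#'
#' @param config a [scene_config()].
#' @return a list of class `scene_bundle` with elements `bands` (named list
#'   G/R/RE/NIR of `wl_raster`), `truth_lai`, `truth_ph_cm`, `truth_mask`
#'   (1 = wheat, 0 = soil), `dsm0`, `dsm1`, `points` (data frame), `config`.
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, {
    nr <- config$height; nc <- config$width
    res <- config$resolution

    # wheat mask: full field minus vertical bare strips
    mask <- matrix(TRUE, nr, nc)
    if (config$soil_strip_every > 0 && config$soil_strip_width > 0 &&
        config$soil_strip_every <= nc) {
      starts <- seq(config$soil_strip_every, nc, by = config$soil_strip_every)
      for (s in starts) {
        cols <- s:min(nc, s + config$soil_strip_width - 1L)
        mask[, cols] <- FALSE
      }
    }

    # LAI: smooth field, rank-mapped onto a truncated normal
    g <- gaussian_random_field(nr, nc, sigma_px = 12)
    u <- (rank(g, ties.method = "first") - 0.5) / length(g)
    mu <- config$lai_mean_sd[1]; sg <- config$lai_mean_sd[2]
    plo <- stats::pnorm(config$lai_range[1], mu, sg)
    phi <- stats::pnorm(config$lai_range[2], mu, sg)
    if (sg > 0 && phi > plo) {
      lai <- stats::qnorm(plo + u * (phi - plo), mu, sg)
    } else {
      lai <- rep(mu, length(u))
    }
    lai <- matrix(pmin(pmax(lai, config$lai_range[1]), config$lai_range[2]), nr, nc)
    lai[!mask] <- 0

    # plant height (cm), linear in LAI on wheat pixels
    ph <- config$ph_slope * lai + config$ph_intercept
    if (config$ph_noise_sd > 0) {
      ph <- ph + matrix(stats::rnorm(nr * nc, 0, config$ph_noise_sd), nr, nc)
    }
    ph <- pmax(ph, 0)
    ph[!mask] <- 0

    # DSM pair: smooth terrain; crop surface adds PH (m) plus sensor noise
    dsm0 <- 25 + 0.5 * gaussian_random_field(nr, nc, sigma_px = 40)
    dsm1 <- dsm0 + ph / 100
    if (config$dsm_noise_sd > 0) {
      dsm1 <- dsm1 + matrix(stats::rnorm(nr * nc, 0, config$dsm_noise_sd), nr, nc)
    }

    # reflectance: Beer-Lambert cover mixing (band-specific extinction so
    # visible bands saturate before the red edge and NIR) + row pattern +
    # noise
    y_m <- (nr - row(lai) + 0.5) * res  # northing of each pixel center
    rowpat <- 1 + config$row_amplitude * sin(2 * pi * y_m / config$row_spacing)
    bands <- vector("list", 4)
    names(bands) <- c("G", "R", "RE", "NIR")
    for (b in seq_len(4)) {
      f <- 1 - exp(-config$extinction_k * config$band_k_scale[b] * lai)
      f[!mask] <- 0
      refl <- f * config$veg_reflectance[b] + (1 - f) * config$soil_reflectance[b]
      refl[mask] <- refl[mask] * rowpat[mask]
      if (config$noise_sd > 0) {
        refl <- refl + matrix(stats::rnorm(nr * nc, 0, config$noise_sd), nr, nc)
      }
      bands[[b]] <- wl_raster(pmin(pmax(refl, 0), 1), 0, 0, res)
    }

    bundle <- structure(list(
      bands = bands,
      truth_lai = wl_raster(lai, 0, 0, res),
      truth_ph_cm = wl_raster(ph, 0, 0, res),
      truth_mask = wl_raster(mask * 1, 0, 0, res),
      dsm0 = wl_raster(dsm0, 0, 0, res),
      dsm1 = wl_raster(dsm1, 0, 0, res),
      config = config
    ), class = "scene_bundle")
    bundle$points <- sample_ground_truth(bundle, n = config$n_points,
                                         seed = config$seed + 1L)
    bundle
  })
}

#' Draw ground-truth sample points from a scene
#'
#' Points are spread quasi-uniformly over the wheat mask by stratified grid
#' jitter: a regular grid of strata is laid over the scene and one random
#' wheat pixel is taken per stratum (falling back to simple random sampling
#' of wheat pixels if the strata cannot supply `n`). Measured LAI is read
#' from the truth raster at the point's pixel; measured PH is the mean
#' truth height within `ph_radius` of the point, mirroring the field
#' protocol of averaging representative plants inside a 50 cm circle. Both
#' carry configurable Gaussian measurement noise.
#'
#' @param bundle a `scene_bundle`.
#' @param n number of points; must not exceed the number of wheat pixels.
#' @param seed integer RNG seed.
#' @param lai_noise_sd,ph_noise_sd measurement noise SDs; default from the
#'   bundle's config.
#' @param ph_radius radius (m) of the plant-height measurement footprint;
#'   0 reads the single containing pixel.
#' @param border pixels of scene margin excluded from sampling (field plots
#'   are laid out in the interior; also keeps moving-window features defined
#'   at every point). Set 0 to allow the full extent.
#' @return data frame `id, x, y, lai, ph_cm` of class `sample_points`.
#' @export
sample_ground_truth <- function(bundle, n = bundle$config$n_points,
                                seed = bundle$config$seed + 1L,
                                lai_noise_sd = bundle$config$lai_noise_sd,
                                ph_noise_sd = bundle$config$ph_meas_noise_sd,
                                border = 2L, ph_radius = 0.5) {
  mask <- bundle$truth_mask$values > 0
  if (border > 0 && nrow(mask) > 2 * border && ncol(mask) > 2 * border) {
    mask[c(seq_len(border), nrow(mask) - seq_len(border) + 1L), ] <- FALSE
    mask[, c(seq_len(border), ncol(mask) - seq_len(border) + 1L)] <- FALSE
  }
  wheat_idx <- which(mask)
  if (!length(wheat_idx)) stop("wheat mask is empty; cannot sample points")
  if (n > length(wheat_idx)) {
    stop("requested ", n, " points but only ", length(wheat_idx), " wheat pixels")
  }
  nr <- nrow(mask); nc <- ncol(mask)
  with_seed(seed, {
    gside <- ceiling(sqrt(n))
    rbreaks <- ceiling(seq_len(nr) / (nr / gside))
    cbreaks <- ceiling(seq_len(nc) / (nc / gside))
    stratum <- matrix(0L, nr, nc)
    stratum[] <- (rbreaks[row(stratum)] - 1L) * gside + cbreaks[col(stratum)]
    chosen <- integer(0)
    strata <- sample(seq_len(gside^2))  # randomized stratum order
    for (s in strata) {
      cand <- wheat_idx[stratum[wheat_idx] == s]
      if (length(cand)) {
        chosen <- c(chosen, if (length(cand) == 1L) cand else sample(cand, 1L))
      }
      if (length(chosen) == n) break
    }
    if (length(chosen) < n) {
      rest <- setdiff(wheat_idx, chosen)
      chosen <- c(chosen, sample(rest, n - length(chosen)))
    }
    rr <- ((chosen - 1L) %% nr) + 1L
    cc <- ((chosen - 1L) %/% nr) + 1L
    res <- bundle$truth_lai$cellsize
    x <- bundle$truth_lai$xll + (cc - 0.5) * res
    y <- bundle$truth_lai$yll + (nr - rr + 0.5) * res
    lai <- bundle$truth_lai$values[cbind(rr, cc)]
    ph <- if (ph_radius > 0) {
      # wheat plants only: soil pixels in the footprint are not measured
      ph_wheat <- bundle$truth_ph_cm
      ph_wheat$values[bundle$truth_mask$values == 0] <- NA_real_
      extract_at_points(ph_wheat, data.frame(x = x, y = y), radius = ph_radius)
    } else {
      bundle$truth_ph_cm$values[cbind(rr, cc)]
    }
    if (lai_noise_sd > 0) lai <- pmax(lai + stats::rnorm(n, 0, lai_noise_sd), 0.01)
    if (ph_noise_sd > 0) ph <- pmax(ph + stats::rnorm(n, 0, ph_noise_sd), 0)
    structure(
      data.frame(id = seq_len(n), x = x, y = y, lai = lai, ph_cm = ph),
      class = c("sample_points", "data.frame")
    )
  })
}

#' Write a scene bundle to disk
#'
#' One ASCII grid per raster (`band_G.asc` ... `dsm1.asc`) and the sample
#' points as `points.csv` (header `id,x,y,lai,ph_cm`).
#'
#' @param bundle a `scene_bundle`.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in names(bundle$bands)) {
    write_ascii_grid(bundle$bands[[b]], file.path(dir, paste0("band_", b, ".asc")))
  }
  write_ascii_grid(bundle$truth_lai, file.path(dir, "truth_lai.asc"))
  write_ascii_grid(bundle$truth_ph_cm, file.path(dir, "truth_ph_cm.asc"))
  write_ascii_grid(bundle$truth_mask, file.path(dir, "truth_mask.asc"))
  write_ascii_grid(bundle$dsm0, file.path(dir, "dsm0.asc"))
  write_ascii_grid(bundle$dsm1, file.path(dir, "dsm1.asc"))
  write_points_csv(bundle$points, file.path(dir, "points.csv"))
  invisible(dir)
}
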
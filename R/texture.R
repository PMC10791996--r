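#' GLCM texture configuration
#'
#' Settings for gray level co-occurrence matrix texture extraction: a 3x3
#' moving window, 64 gray levels and a one-pixel offset are the defaults
#' used throughout the pipeline; the offset direction defaults to (1, 1)
#' (one pixel east, one pixel south — the ENVI-style default shift) and may
#' be set to any of the four canonical one-pixel directions.
#'
#' @param window odd window size in pixels, >= 3.
#' @param levels number of gray levels, >= 2.
#' @param offset integer `c(dx, dy)` pixel shift (dx east, dy south), not
#'   `c(0, 0)`.
#' @param symmetric count each pair in both directions (Haralick convention).
#' @return list of class `glcm_config`.
#' @export
glcm_config <- function(window = 3L, levels = 64L, offset = c(1L, 1L),
                        symmetric = TRUE) {
  window <- as.integer(window); levels <- as.integer(levels)
  offset <- as.integer(offset)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (levels < 2L) stop("levels must be >= 2")
  if (length(offset) != 2L || all(offset == 0L)) {
    stop("offset must be a nonzero (dx, dy) pair")
  }
  structure(list(window = window, levels = levels, offset = offset,
                 symmetric = isTRUE(symmetric)), class = "glcm_config")
}

glcm_stat_names <- function() c("MEA", "VAR", "HOM", "CON", "DIS", "ENT", "SEC", "COR")

#' Quantize a raster to discrete gray levels
#'
#' Linear min-max scaling of the valid values onto `{0, ..., levels - 1}`
#' with half-intervals rounding down, i.e. level = ceiling(u(levels-1) - 1/2)
#' for u = (v - min)/(max - min). Endpoints map to the extreme levels.
#'
#' @param r a `wl_raster` with at least two distinct valid values.
#' @param levels number of gray levels.
#' @return a `wl_raster` of integer levels (stored as doubles; NA preserved).
#' @export
quantize_band <- function(r, levels = 64L) {
  v <- r$values
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  if (!all(is.finite(rng)) || rng[1] == rng[2]) {
    stop("quantization undefined: raster has fewer than 2 distinct valid values")
  }
  u <- (v - rng[1]) / (rng[2] - rng[1])
  q <- ceiling(u * (levels - 1) - 0.5)
  q <- pmin(pmax(q, 0), levels - 1)
  raster_like(r, q)
}

#' GLCM statistics of a single window
#'
#' Builds the (optionally symmetric) normalized co-occurrence matrix
#' p(i, j) of the integer window under the configured offset and returns
#' the eight Haralick statistics: MEA = sum i p, VAR = sum (i - mu)^2 p,
#' HOM = sum p / (1 + (i-j)^2), CON = sum (i-j)^2 p, DIS = sum |i-j| p,
#' ENT = -sum p log p (0 log 0 = 0), SEC = sum p^2, and
#' COR = sum (i - mu_i)(j - mu_j) p / (sigma_i sigma_j), with COR = 0 in
#' zero-variance windows. Pairs involving NA are skipped; if no valid pair
#' exists all statistics are NA.
#'
#' @param window_values integer matrix of gray levels (NA allowed).
#' @param config a [glcm_config()].
#' @return named numeric vector of the 8 statistics.
#' @export
glcm_statistics <- function(window_values, config = glcm_config()) {
  m <- as.matrix(window_values)
  dx <- config$offset[1]; dy <- config$offset[2]
  nr <- nrow(m); nc <- ncol(m)
  rows <- seq_len(nr); cols <- seq_len(nc)
  r1 <- rows[rows + dy >= 1 & rows + dy <= nr]
  c1 <- cols[cols + dx >= 1 & cols + dx <= nc]
  na_out <- stats::setNames(rep(NA_real_, 8), glcm_stat_names())
  if (!length(r1) || !length(c1)) return(na_out)
  i <- as.vector(m[r1, c1, drop = FALSE])
  j <- as.vector(m[r1 + dy, c1 + dx, drop = FALSE])
  ok <- !is.na(i) & !is.na(j)
  i <- i[ok]; j <- j[ok]
  if (!length(i)) return(na_out)
  if (config$symmetric) {
    tmp <- i; i <- c(i, j); j <- c(j, tmp)
  }
  # aggregate counts per distinct (i, j) cell
  key <- paste(i, j)
  cnt <- table(key)
  p <- as.numeric(cnt) / length(i)
  ij <- do.call(rbind, strsplit(names(cnt), " ", fixed = TRUE))
  ii <- as.numeric(ij[, 1]); jj <- as.numeric(ij[, 2])
  mu_i <- sum(ii * p); mu_j <- sum(jj * p)
  var_i <- sum((ii - mu_i)^2 * p); var_j <- sum((jj - mu_j)^2 * p)
  d <- ii - jj
  denom <- sqrt(var_i * var_j)
  c(
    MEA = mu_i,
    VAR = var_i,
    HOM = sum(p / (1 + d^2)),
    CON = sum(d^2 * p),
    DIS = sum(abs(d) * p),
    ENT = -sum(p * log(p)),
    SEC = sum(p^2),
    COR = if (denom > 0) sum((ii - mu_i) * (jj - mu_j) * p) / denom else 0
  )
}

#' Per-pixel GLCM texture stack
#'
#' Quantizes each band and applies [glcm_statistics()] in a moving window,
#' producing 8 statistic rasters per band (32 layers for a 4-band set),
#' named `<band>_<stat>`. Border pixels without a complete window are
#' nodata.
#'
#' @param bands named list of `wl_raster` bands `G, R, RE, NIR`.
#' @param config a [glcm_config()].
#' @return named list of 32 `wl_raster` layers of class `texture_stack`.
#' @export
texture_stack <- function(bands, config = glcm_config()) {
  check_band_set(bands)
  template <- bands$G
  if (config$window > min(dim(template$values))) {
    stop("window (", config$window, ") larger than raster")
  }
  out <- list()
  for (b in names(bands)) {
    v <- bands[[b]]$values
    rng <- suppressWarnings(range(v, na.rm = TRUE))
    q <- if (all(is.finite(rng)) && rng[1] < rng[2]) {
      quantize_band(bands[[b]], config$levels)$values
    } else {
      # constant band: all pixels share one gray level
      v * 0
    }
    qi <- matrix(as.integer(round(q)), nrow(q), ncol(q))
    layers <- glcm_texture_cpp(qi, config$window, config$levels,
                               config$offset[1], config$offset[2],
                               config$symmetric)
    for (s in glcm_stat_names()) {
      out[[paste0(b, "_", s)]] <- raster_like(template, layers[[s]])
    }
  }
  structure(out, class = c("texture_stack", "list"), config = config)
}

#' Enumerate texture-index definitions over a 32-layer stack
#'
#' Builds the full candidate set of texture indices combining two distinct
#' texture layers T1, T2: normalized difference NDTI = (T1-T2)/(T1+T2),
#' difference DTI = T1-T2, and ratio RTI = T1/T2. NDTI and DTI are taken
#' over unordered layer pairs (swapping arguments only flips the sign), RTI
#' over ordered pairs (RTI(T1,T2) = 1/RTI(T2,T1) is a distinct predictor).
#' A 32-layer stack yields 496 + 496 + 992 = 1984 definitions in a
#' deterministic canonical order.
#'
#' @param layer_names character vector of layer names (e.g.
#'   `names(texture_stack(...))`), or a `texture_stack`.
#' @return data frame with columns `kind, t1, t2, name`.
#' @export
enumerate_texture_indices <- function(layer_names) {
  if (inherits(layer_names, "texture_stack")) layer_names <- names(layer_names)
  n <- length(layer_names)
  stopifnot(n >= 2)
  pairs_u <- utils::combn(n, 2)
  defs <- list(
    data.frame(kind = "NDTI",
               t1 = layer_names[pairs_u[1, ]], t2 = layer_names[pairs_u[2, ]]),
    data.frame(kind = "DTI",
               t1 = layer_names[pairs_u[1, ]], t2 = layer_names[pairs_u[2, ]])
  )
  idx <- expand.grid(a = seq_len(n), b = seq_len(n))
  idx <- idx[idx$a != idx$b, ]
  idx <- idx[order(idx$a, idx$b), ]
  defs[[3]] <- data.frame(kind = "RTI",
                          t1 = layer_names[idx$a], t2 = layer_names[idx$b])
  out <- do.call(rbind, defs)
  out$name <- paste0(out$kind, "_", out$t1, ".", out$t2)
  rownames(out) <- NULL
  out
}

ti_eval <- function(kind, t1, t2) {
  out <- switch(kind,
    NDTI = (t1 - t2) / (t1 + t2),
    DTI  = t1 - t2,
    RTI  = t1 / t2,
    stop("unknown texture index kind '", kind, "'")
  )
  out[!is.finite(out)] <- NA_real_
  out
}

#' Compute a texture-index raster
#'
#' @param def one row of [enumerate_texture_indices()] output (or any list
#'   with `kind`, `t1`, `t2`).
#' @param stack a `texture_stack`.
#' @return a `wl_raster`; NDTI with T1+T2 = 0 and RTI with T2 = 0 are nodata.
#' @export
compute_texture_index <- function(def, stack) {
  if (is.data.frame(def)) def <- as.list(def[1, ])
  if (is.null(stack[[def$t1]]) || is.null(stack[[def$t2]])) {
    stop("texture layers not found in stack: ", def$t1, ", ", def$t2)
  }
  raster_like(stack[[def$t1]],
              ti_eval(def$kind, stack[[def$t1]]$values, stack[[def$t2]]$values))
}

#' Compute texture-index values from a matrix of texture-layer values
#'
#' Point-level analogue of [compute_texture_index()]: given an
#' n-samples x 32-layers matrix of texture statistics (columns named as in
#' the stack), evaluates every definition and returns an n x n_def matrix
#' with columns named by definition.
#'
#' @param defs data frame from [enumerate_texture_indices()].
#' @param layer_values numeric matrix with named columns.
#' @return numeric matrix of texture-index values.
#' @export
texture_index_values <- function(defs, layer_values) {
  stopifnot(all(unique(c(defs$t1, defs$t2)) %in% colnames(layer_values)))
  out <- matrix(NA_real_, nrow(layer_values), nrow(defs),
                dimnames = list(NULL, defs$name))
  for (k in seq_len(nrow(defs))) {
    out[, k] <- ti_eval(defs$kind[k],
                        layer_values[, defs$t1[k]],
                        layer_values[, defs$t2[k]])
  }
  out
}

#' Write texture-index definitions as CSV
#'
#' @param defs data frame from [enumerate_texture_indices()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_ti_defs <- function(defs, path) {
  utils::write.csv(defs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
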
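#' Georeferenced raster container
#'
#' A minimal single-band raster: a numeric matrix plus an affine square-cell
#' georeference. Row 1 of the matrix is the northernmost row; column 1 the
#' westernmost column. Map coordinates are in meters. Missing data is carried
#' as `NA` internally and mapped to a nodata sentinel only on file write.
#'
#' @param values numeric matrix (row 1 = north).
#' @param xll,yll map coordinates of the lower-left corner of the grid (m).
#' @param cellsize cell edge length (m/pixel); cells are square.
#' @param crs free-form coordinate reference identifier (not interpreted).
#' @return an object of class `wl_raster`.
#' @examples
#' r <- wl_raster(matrix(1:6, 2, 3), xll = 0, yll = 0, cellsize = 0.1)
#' raster_extent(r)
#' @export
wl_raster <- function(values, xll = 0, yll = 0, cellsize = 0.1, crs = "local") {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(is.numeric(values) || is.logical(values))
  if (!is.finite(cellsize) || cellsize <= 0) {
    stop("cellsize must be a positive finite number")
  }
  storage.mode(values) <- "double"
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize, crs = crs),
    class = "wl_raster"
  )
}

#' @export
print.wl_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<wl_raster> %d rows x %d cols @ %g m | origin (%g, %g) | crs: %s\n",
    nrow(v), ncol(v), x$cellsize, x$xll, x$yll, x$crs
  ))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  if (all(is.finite(rng))) {
    cat(sprintf("  values: [%g, %g], %d NA\n", rng[1], rng[2], sum(is.na(v))))
  } else {
    cat("  values: all NA\n")
  }
  invisible(x)
}

#' @export
dim.wl_raster <- function(x) dim(x$values)

#' Raster extent
#'
#' @param r a `wl_raster`.
#' @return named vector `xmin, xmax, ymin, ymax` (outer cell edges, m).
#' @export
raster_extent <- function(r) {
  c(
    xmin = r$xll, xmax = r$xll + ncol(r$values) * r$cellsize,
    ymin = r$yll, ymax = r$yll + nrow(r$values) * r$cellsize
  )
}

#' Map coordinates of cell centers
#'
#' @param r a `wl_raster`.
#' @return list with vectors `x` (per column) and `y` (per row; row 1 = north).
#' @export
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  list(
    x = r$xll + (seq_len(nc) - 0.5) * r$cellsize,
    y = r$yll + (nr - seq_len(nr) + 0.5) * r$cellsize
  )
}

# map (x, y) -> (row, col) of containing cell; pixel-center convention:
# a point on a shared edge belongs to the cell whose index floor() yields.
xy_to_rowcol <- function(r, x, y) {
  col <- floor((x - r$xll) / r$cellsize) + 1L
  row <- floor((r$yll + nrow(r$values) * r$cellsize - y) / r$cellsize) + 1L
  # points exactly on the top/right outer edge are pulled into the last cell
  col[x == r$xll + ncol(r$values) * r$cellsize] <- ncol(r$values)
  row[y == r$yll] <- nrow(r$values)
  cbind(row = as.integer(row), col = as.integer(col))
}

same_grid <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

raster_like <- function(template, values) {
  wl_raster(values, template$xll, template$yll, template$cellsize, template$crs)
}

#' Read an ESRI ASCII grid
#'
#' Reads a single-band raster from the plain-text ESRI ASCII grid format
#' (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value header followed by
#' row-major values, north row first). Nodata cells become `NA`.
#'
#' @param path file path.
#' @param crs coordinate reference identifier to attach (the format stores none).
#' @return a `wl_raster`.
#' @export
read_ascii_grid <- function(path, crs = "local") {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    kv <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("not an ESRI ASCII grid: missing header fields in ", path)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, what = double(), skip = 6L, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop("ASCII grid ", path, ": expected ", nr * nc, " values, got ", length(vals))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  wl_raster(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, crs)
}

#' Write an ESRI ASCII grid
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces IEEE doubles bit-exactly.
#'
#' @param r a `wl_raster`.
#' @param path destination file path.
#' @param nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  v <- r$values
  if (any(v == nodata, na.rm = TRUE)) {
    stop("raster contains the nodata sentinel ", nodata, " as a real value")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.17g", r$xll),
    sprintf("yllcorner %.17g", r$yll),
    sprintf("cellsize %.17g", r$cellsize),
    sprintf("NODATA_value %.17g", nodata)
  ), con)
  v[is.na(v)] <- nodata
  for (i in seq_len(nrow(v))) {
    writeLines(paste(sprintf("%.17g", v[i, ]), collapse = " "), con)
  }
  invisible(path)
}

# Keys cubic convolution kernel, a = -1/2 (the classic image-resampling choice)
cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  w <- numeric(length(t))
  i1 <- t <= 1
  w[i1] <- (a + 2) * t[i1]^3 - (a + 3) * t[i1]^2 + 1
  i2 <- t > 1 & t < 2
  w[i2] <- a * (t[i2]^3 - 5 * t[i2]^2 + 8 * t[i2] - 4)
  w
}

# 1-D cubic interpolation of columns of a matrix at fractional row positions.
# pos: vector of fractional source indices (1-based, cell-center).
cubic_interp_rows <- function(m, pos) {
  n <- nrow(m)
  base <- floor(pos)
  frac <- pos - base
  out <- matrix(0, length(pos), ncol(m))
  wsum <- matrix(0, length(pos), ncol(m))
  na_hit <- matrix(FALSE, length(pos), ncol(m))
  for (k in -1:2) {
    idx <- pmin(pmax(base + k, 1L), n)  # replicate borders
    w <- cubic_kernel(k - frac)
    rows <- m[idx, , drop = FALSE]
    hit <- is.na(rows) & abs(w) > 1e-12
    na_hit <- na_hit | hit
    rows[is.na(rows)] <- 0
    out <- out + w * rows
    wsum <- wsum + w
  }
  out <- out / wsum
  out[na_hit] <- NA_real_
  out
}

#' Resample a raster by cubic convolution
#'
#' Separable Keys cubic-convolution interpolation (a = -1/2) to a new square
#' grid at `target_resolution`, anchored at the same lower-left corner. Cells
#' whose interpolation stencil touches nodata become nodata; borders use
#' edge replication.
#'
#' @param r a `wl_raster`.
#' @param target_resolution output cell size (m/pixel), > 0.
#' @return a `wl_raster` covering the same extent.
#' @export
resample_cubic <- function(r, target_resolution) {
  stopifnot(target_resolution > 0)
  v <- r$values
  if (length(v) == 0) stop("cannot resample an empty raster")
  ext <- raster_extent(r)
  nc_out <- max(1L, as.integer(round((ext["xmax"] - ext["xmin"]) / target_resolution)))
  nr_out <- max(1L, as.integer(round((ext["ymax"] - ext["ymin"]) / target_resolution)))
  if (nr_out == nrow(v) && nc_out == ncol(v)) {
    return(wl_raster(v, r$xll, r$yll, target_resolution, r$crs))
  }
  # fractional source indices of output cell centers
  x_out <- r$xll + (seq_len(nc_out) - 0.5) * target_resolution
  y_out <- ext["ymax"] - (seq_len(nr_out) - 0.5) * target_resolution
  col_pos <- (x_out - r$xll) / r$cellsize + 0.5
  row_pos <- (ext["ymax"] - y_out) / r$cellsize + 0.5
  tmp <- cubic_interp_rows(v, row_pos)            # nr_out x nc_in
  out <- t(cubic_interp_rows(t(tmp), col_pos))    # nr_out x nc_out
  wl_raster(out, r$xll, r$yll, target_resolution, r$crs)
}

#' Extract raster values at sample points
#'
#' With `radius = 0` the value of the cell containing each point is returned
#' (pixel-center convention). With `radius > 0` the mean of all valid cells
#' whose centers fall within `radius` meters of the point is returned.
#'
#' @param r a `wl_raster`.
#' @param points data frame with columns `x`, `y` and optionally `id`.
#' @param radius extraction radius in meters (>= 0).
#' @return numeric vector, one value per point.
#' @export
extract_at_points <- function(r, points, radius = 0) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  ids <- if ("id" %in% names(points)) points$id else seq_len(nrow(points))
  ext <- raster_extent(r)
  bad <- points$x < ext["xmin"] | points$x > ext["xmax"] |
    points$y < ext["ymin"] | points$y > ext["ymax"]
  if (any(bad)) {
    stop("point(s) outside raster extent: ", paste(ids[bad], collapse = ", "))
  }
  if (radius <= 0) {
    rc <- xy_to_rowcol(r, points$x, points$y)
    return(r$values[cbind(rc[, "row"], rc[, "col"])])
  }
  ctr <- cell_centers(r)
  # small relative slack so cells exactly on the disc boundary are included
  # regardless of floating-point noise in the map coordinates
  r2max <- radius^2 * (1 + 1e-9)
  vapply(seq_len(nrow(points)), function(i) {
    dx <- ctr$x - points$x[i]
    dy <- ctr$y - points$y[i]
    cols <- which(dx^2 <= r2max)
    rows <- which(dy^2 <= r2max)
    if (!length(cols) || !length(rows)) return(NA_real_)
    d2 <- outer(dy[rows]^2, dx[cols]^2, `+`)
    vals <- r$values[rows, cols, drop = FALSE][d2 <= r2max]
    mean(vals, na.rm = TRUE)
  }, numeric(1))
}

#' Write sample points to CSV
#'
#' Header `id,x,y,lai,ph_cm`, full double precision.
#'
#' @param points data frame with columns `id, x, y, lai, ph_cm`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(points, path) {
  stopifnot(all(c("id", "x", "y", "lai", "ph_cm") %in% names(points)))
  utils::write.csv(points[, c("id", "x", "y", "lai", "ph_cm")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sample points from CSV
#'
#' @param path CSV with header `id,x,y,lai,ph_cm`.
#' @return data frame.
#' @export
read_points_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
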
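# shared fixtures and independent oracles, built in code at test time

# small default scene, cached per session
small_scene <- local({
  cache <- new.env()
  function(seed = 7, width = 96, height = 96, n_points = 40, ...) {
    key <- paste(seed, width, height, n_points, ...)
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_scene(scene_config(
        width = width, height = height, seed = seed, n_points = n_points, ...))
    }
    cache[[key]]
  }
})

# a 4-band set of constant-free random rasters on a shared grid
random_bands <- function(nr = 12, nc = 12, seed = 1) {
  set.seed(seed)
  bands <- lapply(c(G = 0.1, R = 0.1, RE = 0.25, NIR = 0.4), function(base) {
    wl_raster(matrix(runif(nr * nc, base, base + 0.3), nr, nc), 0, 0, 0.1)
  })
  names(bands) <- c("G", "R", "RE", "NIR")
  bands
}

# brute-force GLCM oracle: explicit double loop over all pixel pairs,
# integer co-occurrence counts, then direct evaluation of the 8 statistics
glcm_oracle <- function(m, dx, dy, symmetric = TRUE) {
  nr <- nrow(m); nc <- ncol(m)
  is <- c(); js <- c()
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + dy; c2 <- c + dx
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          !is.na(m[r, c]) && !is.na(m[r2, c2])) {
        is <- c(is, m[r, c]); js <- c(js, m[r2, c2])
        if (symmetric) { is <- c(is, m[r2, c2]); js <- c(js, m[r, c]) }
      }
    }
  }
  if (!length(is)) return(setNames(rep(NA_real_, 8),
                                   c("MEA", "VAR", "HOM", "CON",
                                     "DIS", "ENT", "SEC", "COR")))
  n <- length(is)
  lev <- sort(unique(c(is, js)))
  P <- matrix(0, length(lev), length(lev))
  for (k in seq_len(n)) {
    a <- match(is[k], lev); b <- match(js[k], lev)
    P[a, b] <- P[a, b] + 1
  }
  P <- P / n
  mea <- 0; hom <- 0; con <- 0; dis <- 0; ent <- 0; sec <- 0
  mj <- 0
  for (a in seq_along(lev)) for (b in seq_along(lev)) {
    p <- P[a, b]
    if (p == 0) next
    i <- lev[a]; j <- lev[b]
    mea <- mea + i * p; mj <- mj + j * p
    hom <- hom + p / (1 + (i - j)^2)
    con <- con + (i - j)^2 * p
    dis <- dis + abs(i - j) * p
    ent <- ent - p * log(p)
    sec <- sec + p^2
  }
  var <- 0; vj <- 0; cov <- 0
  for (a in seq_along(lev)) for (b in seq_along(lev)) {
    p <- P[a, b]
    if (p == 0) next
    i <- lev[a]; j <- lev[b]
    var <- var + (i - mea)^2 * p
    vj <- vj + (j - mj)^2 * p
    cov <- cov + (i - mea) * (j - mj) * p
  }
  cor <- if (var * vj > 0) cov / sqrt(var * vj) else 0
  c(MEA = mea, VAR = var, HOM = hom, CON = con, DIS = dis,
    ENT = ent, SEC = sec, COR = cor)
}

# exhaustive SPXY reference: explicit O(N^3) loops, no vectorization shared
# with the implementation
spxy_reference <- function(x, y, cal_fraction = 0.7, standardize = TRUE) {
  n <- length(y)
  x <- as.matrix(x)
  if (standardize) {
    for (j in seq_len(ncol(x))) {
      s <- sd(x[, j])
      if (is.finite(s) && s > 0) x[, j] <- (x[, j] - mean(x[, j])) / s
      else x[, j] <- 0
    }
  }
  dx <- matrix(0, n, n); dy <- matrix(0, n, n)
  for (p in seq_len(n)) for (q in seq_len(n)) {
    dx[p, q] <- sqrt(sum((x[p, ] - x[q, ])^2))
    dy[p, q] <- sqrt((y[p] - y[q])^2)
  }
  mx <- max(dx); my <- max(dy)
  d <- (if (mx > 0) dx / mx else dx) + (if (my > 0) dy / my else dy)
  n_cal <- max(2L, min(as.integer(round(cal_fraction * n)), n - 1L))
  # seed pair: maximal d, scanning in lowest-index order
  bi <- 1L; bj <- 2L; best <- -Inf
  for (p in seq_len(n - 1)) for (q in (p + 1):n) {
    if (d[p, q] > best) { best <- d[p, q]; bi <- p; bj <- q }
  }
  sel <- c(bi, bj)
  while (length(sel) < n_cal) {
    bestk <- NA; bestd <- -Inf
    for (k in seq_len(n)) {
      if (k %in% sel) next
      mind <- Inf
      for (s in sel) if (d[k, s] < mind) mind <- d[k, s]
      if (mind > bestd) { bestd <- mind; bestk <- k }
    }
    sel <- c(sel, bestk)
  }
  list(calibration = sort(sel), validation = setdiff(seq_len(n), sort(sel)))
}

# numerical gradient of f at theta by central differences
numerical_gradient <- function(f, theta, eps = 1e-5) {
  g <- numeric(length(theta))
  for (k in seq_along(theta)) {
    up <- theta; up[k] <- up[k] + eps
    dn <- theta; dn[k] <- dn[k] - eps
    g[k] <- (f(up) - f(dn)) / (2 * eps)
  }
  g
}
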
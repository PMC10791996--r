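test_that("quantization maps endpoints to extremes and thresholds at midpoints", {
  r01 <- wl_raster(matrix(c(0, 1), 2, 2), 0, 0, 1)
  expect_equal(sort(unique(as.vector(quantize_band(r01, 64)$values))), c(0, 63))
  # linear ramp, 2 levels: lower half -> 0, upper half -> 1
  ramp <- wl_raster(matrix(seq(0, 1, length.out = 100), 10, 10), 0, 0, 1)
  q2 <- quantize_band(ramp, 2)$values
  expect_equal(as.vector(q2), as.numeric(seq(0, 1, length.out = 100) > 0.5))
  # {0, 0.5, 1} at 64 levels -> {0, 31, 63} (half-interval rounds down)
  r3 <- wl_raster(matrix(c(0, 0.5, 1, 0), 2, 2), 0, 0, 1)
  expect_setequal(unique(as.vector(quantize_band(r3, 64)$values)), c(0, 31, 63))
  expect_error(quantize_band(wl_raster(matrix(5, 3, 3)), 64), "distinct")
})

test_that("constant window yields the degenerate single-cell GLCM", {
  s <- glcm_statistics(matrix(3L, 3, 3), glcm_config(offset = c(1, 0)))
  expect_equal(s[["CON"]], 0)
  expect_equal(s[["DIS"]], 0)
  expect_equal(s[["ENT"]], 0)
  expect_equal(s[["SEC"]], 1)
  expect_equal(s[["HOM"]], 1)
  expect_equal(s[["MEA"]], 3)
  expect_equal(s[["COR"]], 0)  # zero-variance convention
})

test_that("the 6-pair worked window reproduces hand-enumerated statistics", {
  # pairs under offset (1,0): (0,0)x1, (0,1)x2, (1,1)x3; symmetrized n = 12
  w <- matrix(c(0, 0, 1,
                0, 1, 1,
                1, 1, 1), 3, 3, byrow = TRUE)
  s <- glcm_statistics(w, glcm_config(levels = 2, offset = c(1, 0)))
  expect_equal(s[["CON"]], 1 / 3)
  expect_equal(s[["SEC"]], 1 / 3)
  expect_equal(s[["DIS"]], 1 / 3)
  # p = {(0,0): 1/6, (0,1): 1/6, (1,0): 1/6, (1,1): 1/2}
  expect_equal(s[["ENT"]], -(3 * (1 / 6) * log(1 / 6) + (1 / 2) * log(1 / 2)))
})

test_that("glcm_statistics equals the brute-force pair-enumeration oracle", {
  set.seed(42)
  offsets <- list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (rep in 1:50) {
    nr <- sample(3:7, 1); nc <- sample(3:7, 1)
    m <- matrix(sample(0:5, nr * nc, replace = TRUE), nr, nc)
    off <- offsets[[sample(4, 1)]]
    sym <- sample(c(TRUE, FALSE), 1)
    got <- glcm_statistics(m, glcm_config(levels = 6, offset = off, symmetric = sym))
    want <- glcm_oracle(m, off[1], off[2], sym)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("moving-window rasters agree with per-window statistics", {
  set.seed(5)
  bands <- random_bands(9, 9, seed = 5)
  cfg <- glcm_config(window = 3, levels = 8, offset = c(1, 1))
  st <- texture_stack(bands, cfg)
  expect_length(st, 32)
  expect_named(st, as.vector(outer(c("G", "R", "RE", "NIR"),
                                   c("MEA", "VAR", "HOM", "CON",
                                     "DIS", "ENT", "SEC", "COR"),
                                   paste, sep = "_"))[order(rep(1:4, 8))])
  q <- quantize_band(bands$NIR, 8)$values
  for (ctr in list(c(2, 2), c(5, 5), c(8, 3))) {
    w <- q[(ctr[1] - 1):(ctr[1] + 1), (ctr[2] - 1):(ctr[2] + 1)]
    want <- glcm_statistics(w, cfg)
    for (s in names(want)) {
      expect_equal(st[[paste0("NIR_", s)]]$values[ctr[1], ctr[2]], want[[s]],
                   tolerance = 1e-12, info = s)
    }
  }
  # border pixels have no complete window
  expect_true(all(is.na(st$G_MEA$values[1, ])))
  expect_true(all(is.na(st$G_MEA$values[, 1])))
})

test_that("texture probabilities behave: bounds hold across random windows", {
  set.seed(8)
  for (rep in 1:40) {
    m <- matrix(sample(0:7, 25, replace = TRUE), 5, 5)
    s <- glcm_statistics(m, glcm_config(levels = 8))
    expect_true(s[["SEC"]] > 0 && s[["SEC"]] <= 1)
    expect_true(s[["HOM"]] > 0 && s[["HOM"]] <= 1)
    expect_gte(s[["ENT"]], 0)
    expect_true(s[["COR"]] >= -1 - 1e-12 && s[["COR"]] <= 1 + 1e-12)
    expect_gte(s[["VAR"]], 0)
  }
})

test_that("constant band gives constant MEA and zero CON; a perturbation is local", {
  mk <- function(v) wl_raster(v, 0, 0, 0.1)
  const <- matrix(0.3, 11, 11)
  bands <- list(G = mk(const), R = mk(const), RE = mk(const), NIR = mk(const))
  st <- texture_stack(bands, glcm_config())
  inner <- 2:10
  expect_true(all(st$G_CON$values[inner, inner] == 0))
  expect_equal(length(unique(as.vector(st$G_MEA$values[inner, inner]))), 1L)
  # single perturbed pixel: CON nonzero only within window+offset reach
  pert <- const; pert[6, 6] <- 0.9
  bands$NIR <- mk(pert)
  st2 <- texture_stack(bands, glcm_config())
  con <- st2$NIR_CON$values[inner, inner]
  nonzero <- which(con > 0, arr.ind = TRUE)
  expect_true(all(abs(nonzero[, 1] + 1 - 6) <= 2 & abs(nonzero[, 2] + 1 - 6) <= 2))
  expect_gt(nrow(nonzero), 0)
  expect_error(texture_stack(bands, glcm_config(window = 13)), "window")
})
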
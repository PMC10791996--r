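test_that("degenerate LAI range gives a constant field on wheat pixels", {
  b <- generate_scene(scene_config(width = 48, height = 48, seed = 1,
                                   lai_range = c(2, 2), n_points = 5))
  wheat <- b$truth_mask$values > 0
  expect_true(all(b$truth_lai$values[wheat] == 2))
  expect_true(all(b$truth_lai$values[!wheat] == 0))
})

test_that("noise-free plant height follows the configured linear rule exactly", {
  b <- generate_scene(scene_config(width = 48, height = 48, seed = 2,
                                   ph_noise_sd = 0, ph_slope = 5,
                                   ph_intercept = 10, n_points = 5))
  wheat <- b$truth_mask$values > 0
  expect_equal(b$truth_ph_cm$values[wheat],
               5 * b$truth_lai$values[wheat] + 10)
})

test_that("identical seeds give bit-identical bundles; config errors are caught", {
  cfg <- scene_config(width = 40, height = 40, seed = 42, n_points = 8)
  b1 <- generate_scene(cfg)
  b2 <- generate_scene(cfg)
  expect_identical(b1$bands$NIR$values, b2$bands$NIR$values)
  expect_identical(b1$dsm1$values, b2$dsm1$values)
  expect_identical(b1$points, b2$points)
  expect_error(scene_config(extinction_k = NaN), "non-finite")
  expect_error(scene_config(n_points = 2), "n_points")
  expect_error(scene_config(veg_reflectance = c(0.1, 0.2, 0.3, 1.4)), "reflectance")
})

test_that("sampled LAI matches the configured distribution for large n", {
  b <- small_scene(seed = 5, width = 200, height = 200, n_points = 300)
  pts <- b$points
  expect_lt(abs(mean(pts$lai) - 3.89) / 3.89, 0.15)
  expect_lt(abs(sd(pts$lai) - 1.93) / 1.93, 0.15)
  expect_true(all(pts$lai >= 0.01 & pts$lai <= 8.57 + 1))
})

test_that("a single noise-free point reads the truth raster identically", {
  b <- small_scene(seed = 3)
  p <- sample_ground_truth(b, n = 1, seed = 9, lai_noise_sd = 0,
                           ph_noise_sd = 0, ph_radius = 0)
  expect_equal(p$lai, extract_at_points(b$truth_lai, p, radius = 0))
  expect_equal(p$ph_cm, extract_at_points(b$truth_ph_cm, p, radius = 0))
  # with the field footprint, PH is the 0.5 m wheat-pixel mean
  p2 <- sample_ground_truth(b, n = 1, seed = 9, lai_noise_sd = 0,
                            ph_noise_sd = 0)
  masked <- b$truth_ph_cm
  masked$values[b$truth_mask$values == 0] <- NA
  expect_equal(p2$ph_cm, extract_at_points(masked, p2, radius = 0.5))
  expect_identical(p, sample_ground_truth(b, n = 1, seed = 9, lai_noise_sd = 0,
                                          ph_noise_sd = 0, ph_radius = 0))
})

test_that("points show the field structure: positive PH-LAI correlation, spread over mask", {
  b <- small_scene(seed = 11, width = 128, height = 128, n_points = 79)
  pts <- b$points
  expect_equal(nrow(pts), 79)
  expect_gt(cor(pts$ph_cm, pts$lai), 0)
  rc <- cbind(
    row = floor((raster_extent(b$truth_mask)["ymax"] - pts$y) / 0.1) + 1,
    col = floor(pts$x / 0.1) + 1
  )
  expect_true(all(b$truth_mask$values[rc] > 0))
  expect_error(sample_ground_truth(b, n = 1e7), "wheat pixels")
})

test_that("cover fraction and reflectance stay within physical bounds; NDVI tracks LAI", {
  b <- small_scene(seed = 13, width = 128, height = 128, n_points = 79)
  f <- 1 - exp(-b$config$extinction_k * b$truth_lai$values)
  expect_true(all(f >= 0 & f < 1))
  for (band in b$bands) {
    expect_true(all(band$values >= 0 & band$values <= 1))
  }
  ndvi <- compute_vi(b$bands, "NDVI")
  wheat <- b$truth_mask$values > 0
  expect_gt(cor(ndvi$values[wheat], b$truth_lai$values[wheat],
                method = "spearman"), 0.6)
})

test_that("scene bundles survive a disk round-trip", {
  b <- generate_scene(scene_config(width = 32, height = 32, seed = 6, n_points = 5))
  dir <- withr::local_tempdir()
  write_scene(b, dir)
  b2 <- wheatlai:::load_scene_dir(dir)
  expect_identical(b2$bands$G$values, b$bands$G$values)
  expect_identical(b2$dsm0$values, b$dsm0$values)
  expect_equal(b2$points$lai, b$points$lai)
})
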
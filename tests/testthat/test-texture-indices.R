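test_that("enumeration counts follow the unordered/ordered pairing scheme", {
  # 32 layers: C(32,2) NDTI + C(32,2) DTI + 32*31 RTI = 496 + 496 + 992
  defs32 <- enumerate_texture_indices(paste0("L", 1:32))
  expect_equal(nrow(defs32), 1984)
  expect_equal(as.vector(table(defs32$kind)[c("NDTI", "DTI", "RTI")]),
               c(496, 496, 992))
  defs4 <- enumerate_texture_indices(paste0("L", 1:4))
  expect_equal(nrow(defs4), 24)
  expect_equal(as.vector(table(defs4$kind)[c("NDTI", "DTI", "RTI")]), c(6, 6, 12))
  defs2 <- enumerate_texture_indices(c("a", "b"))
  expect_equal(nrow(defs2), 4)
  expect_setequal(defs2$name,
                  c("NDTI_a.b", "DTI_a.b", "RTI_a.b", "RTI_b.a"))
  # deterministic canonical ordering, no sign-equivalent duplicates
  expect_identical(defs32, enumerate_texture_indices(paste0("L", 1:32)))
  nd <- defs32[defs32$kind == "NDTI", ]
  expect_false(any(duplicated(t(apply(cbind(nd$t1, nd$t2), 1, sort)))))
})

test_that("texture-index arithmetic matches hand evaluation and its contracts", {
  t1 <- wl_raster(matrix(3, 2, 2)); t2 <- wl_raster(matrix(1, 2, 2))
  stack <- list(A = t1, B = t2)
  expect_equal(compute_texture_index(list(kind = "NDTI", t1 = "A", t2 = "B"),
                                     stack)$values[1, 1], 0.5)
  expect_equal(compute_texture_index(list(kind = "DTI", t1 = "A", t2 = "B"),
                                     stack)$values[1, 1], 2)
  expect_equal(compute_texture_index(list(kind = "RTI", t1 = "A", t2 = "B"),
                                     stack)$values[1, 1], 3)
  # identical layers: NDTI = 0, DTI = 0, RTI = 1
  stack2 <- list(A = t1, B = t1)
  expect_true(all(compute_texture_index(list(kind = "NDTI", t1 = "A", t2 = "B"),
                                        stack2)$values == 0))
  expect_true(all(compute_texture_index(list(kind = "DTI", t1 = "A", t2 = "B"),
                                        stack2)$values == 0))
  expect_true(all(compute_texture_index(list(kind = "RTI", t1 = "A", t2 = "B"),
                                        stack2)$values == 1))
  # singularities are nodata
  z <- wl_raster(matrix(0, 2, 2))
  expect_true(all(is.na(compute_texture_index(
    list(kind = "RTI", t1 = "A", t2 = "Z"), list(A = t1, Z = z))$values)))
  neg <- wl_raster(matrix(-3, 2, 2))
  expect_true(all(is.na(compute_texture_index(
    list(kind = "NDTI", t1 = "A", t2 = "N"), list(A = t1, N = neg))$values)))
  expect_error(compute_texture_index(list(kind = "NDTI", t1 = "A", t2 = "missing"),
                                     stack), "not found")
})

test_that("antisymmetry and reciprocity hold pixelwise on random layers", {
  set.seed(12)
  a <- matrix(runif(36, 0.1, 2), 6, 6)
  b <- matrix(runif(36, 0.1, 2), 6, 6)
  stack <- list(A = wl_raster(a), B = wl_raster(b))
  nd_ab <- compute_texture_index(list(kind = "NDTI", t1 = "A", t2 = "B"), stack)$values
  nd_ba <- compute_texture_index(list(kind = "NDTI", t1 = "B", t2 = "A"), stack)$values
  expect_equal(nd_ab, -nd_ba)
  dt_ab <- compute_texture_index(list(kind = "DTI", t1 = "A", t2 = "B"), stack)$values
  dt_ba <- compute_texture_index(list(kind = "DTI", t1 = "B", t2 = "A"), stack)$values
  expect_equal(dt_ab, -dt_ba)
  rt_ab <- compute_texture_index(list(kind = "RTI", t1 = "A", t2 = "B"), stack)$values
  rt_ba <- compute_texture_index(list(kind = "RTI", t1 = "B", t2 = "A"), stack)$values
  expect_equal(rt_ab * rt_ba, matrix(1, 6, 6))
})

test_that("matrix evaluation of definitions matches the raster route", {
  set.seed(3)
  vals <- matrix(runif(5 * 3, 0.5, 2), 5, 3, dimnames = list(NULL, c("p", "q", "s")))
  defs <- enumerate_texture_indices(c("p", "q", "s"))
  got <- texture_index_values(defs, vals)
  expect_equal(dim(got), c(5L, nrow(defs)))
  for (k in sample(nrow(defs), 5)) {
    stack <- lapply(as.data.frame(vals), function(v) wl_raster(matrix(v, 5, 1)))
    want <- compute_texture_index(defs[k, ], stack)$values[, 1]
    expect_equal(unname(got[, k]), want)
  }
})
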
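test_that("slope and aspect follow Horn's stencil", {
  # constant surface: slope identically zero
  flat <- reef_raster(matrix(2.5, 12, 12), meaning = "height")
  sa <- slope_aspect(flat)
  expect_true(all(sa$slope$data[2:11, 2:11] == 0))

  # plane z = x (unit gradient east): interior slope is 45 degrees
  z <- outer(rep(1, 12), (1:12 - 0.5) * 0.001)
  plane <- reef_raster(z, meaning = "height")
  sp <- slope_aspect(plane)
  expect_equal(sp$slope$data[2:11, 2:11],
               matrix(atan(1), 10, 10), tolerance = 1e-10)

  # random surface: equals the loop oracle
  dsm <- random_height_raster(15, 13, seed = 7)
  sa <- slope_aspect(dsm)
  or <- horn_oracle(dsm$data, dsm$cell)
  expect_equal(sa$slope$data, or$slope, tolerance = 1e-12)
  expect_equal(sa$aspect$data, or$aspect, tolerance = 1e-12)

  expect_error(slope_aspect(reef_raster(matrix(0, 2, 5), meaning = "height")),
               "3x3")
})

test_that("normal decomposition yields unit vectors with the stated components", {
  dsm <- random_height_raster(12, 12, seed = 2)
  sa <- slope_aspect(dsm)
  nf <- normals_from_slope_aspect(sa$slope, sa$aspect)
  nrm <- sqrt(nf$nx$data^2 + nf$ny$data^2 + nf$nz$data^2)
  expect_equal(nrm[!is.na(nrm)], rep(1, sum(!is.na(nrm))), tolerance = 1e-6)
  # slope 0 -> (0, 0, 1); slope 90 deg aspect 0 -> (0, 1, 0)
  s0 <- reef_raster(matrix(0, 3, 3), meaning = "scalar")
  a0 <- reef_raster(matrix(0, 3, 3), meaning = "scalar")
  n0 <- normals_from_slope_aspect(s0, a0)
  expect_equal(c(n0$nx$data[1], n0$ny$data[1], n0$nz$data[1]), c(0, 0, 1))
  s9 <- reef_raster(matrix(pi / 2, 3, 3), meaning = "scalar")
  n9 <- normals_from_slope_aspect(s9, a0)
  expect_equal(c(n9$nx$data[1], n9$ny$data[1], n9$nz$data[1]), c(0, 1, 0),
               tolerance = 1e-15)
})

test_that("VRM is zero on flat and uniformly tilted surfaces and in [0,1]", {
  flat <- reef_raster(matrix(1.23, 64, 64), meaning = "height")
  v <- vrm(flat, 21)$vrm$data
  expect_true(all(abs(v[!is.na(v)]) < 1e-12))

  tilted <- reef_raster(outer(rep(1, 40), (1:40) * 0.002), meaning = "height")
  vt <- vrm(tilted, 5)$vrm$data
  expect_true(all(abs(vt[!is.na(vt)]) < 1e-10))

  rough <- random_height_raster(40, 40, seed = 5, scale = 0.02)
  vr <- vrm(rough, 7)$vrm$data
  expect_true(all(vr[!is.na(vr)] >= 0 & vr[!is.na(vr)] <= 1))
})

test_that("VRM equals the brute-force windowed-resultant oracle", {
  dsm <- random_height_raster(31, 31, seed = 9, scale = 0.01)
  v <- vrm(dsm, 5)$vrm$data
  o <- vrm_oracle(dsm$data, dsm$cell, 5)
  expect_equal(v, o, tolerance = 1e-10)
})

test_that("VRM is invariant to height offsets and 90-degree scene rotation", {
  dsm <- random_height_raster(25, 25, seed = 12, scale = 0.01)
  v1 <- vrm(dsm, 5)$vrm$data
  shifted <- reef_raster(dsm$data + 3.7, cell = dsm$cell, meaning = "height")
  expect_equal(vrm(shifted, 5)$vrm$data, v1, tolerance = 1e-9)
  rot <- reef_raster(t(dsm$data[nrow(dsm$data):1, ]), cell = dsm$cell,
                     meaning = "height")
  v2 <- vrm(rot, 5)$vrm$data
  expect_equal(v2, t(v1[nrow(v1):1, ]), tolerance = 1e-9)
})

test_that("nodata inside a window voids the VRM cell; window errors checked", {
  z <- matrix(0.5, 15, 15)
  z[8, 8] <- NA
  v <- vrm(reef_raster(z, meaning = "height"), 3)$vrm$data
  # the 3x3 normal stencil voids normals at rows/cols 7..9; a 3x3 VRM window
  # grows the hole to centers 6..10, while cells outside it stay valid
  expect_true(all(is.na(v[6:10, 6:10])))
  expect_false(anyNA(v[5, 3:13]))
  expect_false(anyNA(v[3, 3:13]))
  expect_error(vrm(reef_raster(z, meaning = "height"), 4), "odd")
  expect_error(vrm(reef_raster(z, meaning = "height"), 17), "larger than grid")
})

test_that("DSM differencing is in mm, antisymmetric, and nodata-propagating", {
  a <- random_height_raster(10, 10, seed = 1)
  b <- random_height_raster(10, 10, seed = 2)
  b$data[3, 3] <- NA
  d <- dsm_difference(b, a)
  expect_equal(d$data[1, 1], (b$data[1, 1] - a$data[1, 1]) * 1000)
  expect_true(is.na(d$data[3, 3]))
  d2 <- dsm_difference(a, b)
  expect_equal(d$data, -d2$data)
  # constant offset
  c10 <- reef_raster(a$data + 0.010, cell = a$cell, meaning = "height")
  expect_equal(dsm_difference(c10, a)$data, matrix(10, 10, 10))
  expect_error(dsm_difference(a, random_height_raster(9, 10)), "co-registration")
})

test_that("change summaries compute robust statistics without truncation", {
  const <- reef_raster(matrix(4.2, 8, 8), meaning = "scalar")
  expect_equal(change_summary(const)$stats$median, 4.2)
  skew <- reef_raster(matrix(c(rep(0, 9), 100), 2, 5), meaning = "scalar")
  cs <- change_summary(skew)
  expect_equal(cs$stats$median, 0)
  expect_equal(cs$stats$mean, 10)  # statistics never truncated at +-50
  expect_equal(sum(cs$histogram$counts), 10)
  m <- reef_raster(matrix(c(rep(1, 5), rep(0, 5)), 2, 5), meaning = "label")
  expect_equal(change_summary(skew, m, class_id = 1)$stats$n, 5L)
  empty <- reef_raster(matrix(NA_real_, 2, 2), meaning = "scalar")
  expect_error(change_summary(empty), "empty selection")
})

test_that("class stratification matches manual subsetting and partitions n", {
  set.seed(8)
  vals <- reef_raster(matrix(rnorm(400), 20, 20), meaning = "scalar")
  mask <- reef_raster(matrix(sample(0:2, 400, TRUE), 20, 20), meaning = "label")
  st <- stratify_by_class(vals, mask)
  for (k in 0:2) {
    sub <- vals$data[mask$data == k]
    expect_equal(st$median[st$class == k], median(sub))
    expect_equal(st$n[st$class == k], length(sub))
  }
  expect_equal(sum(st$n), 400L)
  one <- reef_raster(matrix(1, 20, 20), meaning = "label")
  st1 <- stratify_by_class(vals, one)
  expect_equal(st1$n[st1$class == 1], 400L)
  expect_equal(st1$n[st1$class == 0], 0L)
  expect_true(is.na(st1$median[st1$class == 0]))
})
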
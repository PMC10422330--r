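label_component_count <- function(lab) {
  # 4-connected component count of the non-background mask (flood fill)
  m <- !is.na(lab) & lab > 0
  H <- nrow(m); W <- ncol(m)
  seen <- matrix(FALSE, H, W)
  count <- 0
  for (idx in which(m & !seen)) {
    if (seen[idx]) next
    count <- count + 1
    stack <- idx
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[i]) next
      seen[i] <- TRUE
      r <- (i - 1) %% H + 1; c <- (i - 1) %/% H + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W) {
          j <- (cc - 1) * H + rr
          if (m[j] && !seen[j]) stack <- c(stack, j)
        }
      }
    }
  }
  count
}

test_that("scene generation is deterministic and honors the empty case", {
  p <- scene_params(extent_px = c(96, 96), n_colonies = 3,
                    colony_radius_range = c(0.008, 0.016), seed = 5)
  s1 <- generate_scene(p)
  s2 <- generate_scene(p)
  expect_identical(s1$dsm$data, s2$dsm$data)
  expect_identical(s1$ortho$data, s2$ortho$data)
  expect_identical(s1$labels$data, s2$labels$data)
  expect_identical(s1$truth, s2$truth)

  p0 <- scene_params(extent_px = c(64, 64), n_colonies = 0, rock_fraction = 0,
                     seed = 2)
  s0 <- generate_scene(p0)
  expect_true(all(s0$labels$data == 0))
  expect_true(all(is.finite(s0$dsm$data)))
})

test_that("non-overlapping colonies produce one labeled component each", {
  p <- scene_params(extent_px = c(1024, 1024), n_colonies = 10,
                    colony_radius_range = c(0.05, 0.1), rock_fraction = 0,
                    seed = 21)
  s <- generate_scene(p)
  expect_equal(sum(s$truth$type == "coral"), 10)
  expect_equal(label_component_count(s$labels$data), 10)
})

test_that("epoch evolution applies growth exactly and only on live colonies", {
  s1 <- tiny_scene(seed = 31, extent = 160, n = 4)
  # identity delta changes nothing
  same <- evolve_scene(s1, epoch_delta(0, 0, 0))
  expect_identical(same$dsm$data, s1$dsm$data)
  expect_identical(same$labels$data, s1$labels$data)
  expect_identical(same$ortho$data, s1$ortho$data)

  s2 <- evolve_scene(s1, epoch_delta(growth_mm = 10))
  d <- s2$dsm$data - s1$dsm$data
  live <- s1$labels$data == 1
  expect_equal(max(abs(d[live] - 0.010)), 0, tolerance = 1e-12)
  expect_true(all(d[!live] == 0))
  expect_identical(s2$labels$data, s1$labels$data)
})

test_that("mortality relabels floor(fraction * live) colonies, DSM unchanged", {
  s1 <- tiny_scene(seed = 32, extent = 200, n = 6)
  n_live <- sum(s1$truth$class == 1)
  s2 <- evolve_scene(s1, epoch_delta(mortality_fraction = 0.5, seed = 9))
  expect_identical(s2$dsm$data, s1$dsm$data)
  n_new_dead <- sum(s1$truth$class == 1 & s2$truth$class == 2)
  expect_equal(n_new_dead, floor(0.5 * n_live))
  # relabeled footprints change label raster, others do not
  expect_equal(sum(s1$labels$data == 1) - sum(s2$labels$data == 1),
               sum(s2$labels$data == 2) - sum(s1$labels$data == 2))
})

test_that("removal reverts colonies to substrate and background is conserved", {
  s1 <- tiny_scene(seed = 33, extent = 200, n = 6)
  s2 <- evolve_scene(s1, epoch_delta(growth_mm = 5, mortality_fraction = 0.3,
                                     removal_fraction = 0.3, seed = 4))
  n_coral <- sum(s1$truth$type == "coral")
  expect_equal(sum(s2$truth$removed), floor(0.3 * n_coral))
  # background cells (outside every coral footprint in both epochs) bit-equal
  bg <- s1$labels$data == 0 & s2$labels$data == 0
  removed_any <- s1$labels$data != s2$labels$data
  untouched <- bg & !removed_any
  expect_identical(s2$dsm$data[untouched], s1$dsm$data[untouched])
  expect_identical(s2$ortho$data[, , 2][untouched], s1$ortho$data[, , 2][untouched])
})

test_that("median growth recovery on surviving live cells is exact", {
  s1 <- tiny_scene(seed = 34, extent = 200, n = 6)
  s2 <- evolve_scene(s1, epoch_delta(growth_mm = 10, mortality_fraction = 0.25,
                                     seed = 3))
  change <- dsm_difference(s2$dsm, s1$dsm)
  surviving_live <- s2$labels$data == 1
  expect_equal(median(change$data[surviving_live]), 10, tolerance = 1e-12)
  expect_lt(change_summary(change)$stats$median, 10)
})

test_that("point-cloud sampling matches cell counts, classes and the surface", {
  s <- tiny_scene(seed = 35, extent = 96, n = 2)
  cl <- sample_point_cloud(s, 1L, jitter = FALSE)
  expect_equal(nrow(cl$xyz), 96 * 96)
  # density-1, jitter-0: z equals the cell value, class counts equal cell counts
  expect_equal(cl$xyz[, 3], as.vector(s$dsm$data), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(as.vector(table(cl$class_id)),
               as.vector(table(s$labels$data)))
  # jittered samples stay within interpolation reach of the surface
  cj <- sample_point_cloud(s, 2L, jitter = TRUE, seed = 6)
  expect_equal(nrow(cj$xyz), 2 * 96 * 96)
  zi <- reef3d:::dsm_bilinear(s$dsm, cj$xyz[, 1], cj$xyz[, 2])
  expect_equal(cj$xyz[, 3], zi, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("height-field meshes have the prescribed counts and upward normals", {
  flat <- reef_raster(matrix(0.5, 2, 2), meaning = "height")
  m <- build_mesh(flat)
  expect_equal(nrow(m$vertices), 4)
  expect_equal(nrow(m$faces), 2)

  s <- tiny_scene(seed = 36, extent = 64, n = 1)
  mesh <- build_mesh(s)
  R <- nrow(s$dsm$data); C <- ncol(s$dsm$data)
  expect_equal(nrow(mesh$vertices), R * C)
  expect_equal(nrow(mesh$faces), 2 * (R - 1) * (C - 1))
  fn <- face_normals(mesh)
  expect_true(all(fn[, 3] > 0))
  expect_error(build_mesh(reef_raster(matrix(0, 1, 5), meaning = "height")),
               "mesh error")
})
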
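mk_pair <- function(H, W, seed = 1) {
  set.seed(seed)
  geo <- c(0, H * 0.001)
  list(ortho = reef_raster(array(sample(0:255, H * W * 3, TRUE), c(H, W, 3)),
                           geo, meaning = "rgb"),
       dsm = reef_raster(matrix(rnorm(H * W, 0, 0.01), H, W), geo,
                         meaning = "height"),
       labels = reef_raster(matrix(sample(0:2, H * W, TRUE), H, W), geo,
                            meaning = "label"))
}

test_that("patch counts follow the sliding-window formula", {
  for (ext in c(448L, 896L, 1120L)) {
    r <- mk_pair(ext, ext)
    ps <- extract_patches(r$ortho, r$dsm, r$labels)
    per_axis <- (ext - 448L) %/% 224L + 1L
    expect_equal(length(ps), per_axis^2)
  }
  small <- mk_pair(100, 100)
  expect_error(extract_patches(small$ortho, small$dsm, NULL), "tiling error")
})

test_that("patch counts hold on random extents vs window-origin enumeration", {
  set.seed(17)
  for (i in 1:8) {
    H <- sample(64:160, 1); W <- sample(64:160, 1)
    win <- sample(seq(16, 64, 8), 1); st <- sample(c(8L, 16L, 24L), 1)
    r <- mk_pair(H, W, seed = i)
    ps <- extract_patches(r$ortho, r$dsm, NULL, win, st)
    n_r <- length(seq(0L, H - win, by = st))
    n_c <- length(seq(0L, W - win, by = st))
    expect_equal(length(ps), n_r * n_c)
    expect_true(all(vapply(ps, function(p) all(p$origin %% st == 0), TRUE)))
  }
})

test_that("patches dominated by nodata are dropped", {
  r <- mk_pair(64, 96)
  r$dsm$data[, 1:40] <- NA
  # patches starting at column 0 are fully nodata; at column 32 they are 25%
  # nodata -> kept at the 0.5 threshold, dropped at a 0.2 threshold
  ps <- extract_patches(r$ortho, r$dsm, NULL, 32, 32, max_nodata_frac = 0.5)
  expect_true(all(vapply(ps, function(p) p$origin[2] >= 32, TRUE)))
  strict <- extract_patches(r$ortho, r$dsm, NULL, 32, 32, max_nodata_frac = 0.2)
  expect_true(all(vapply(strict, function(p) p$origin[2] >= 64, TRUE)))
})

test_that("augmentation rotations are exact, involutive and count-preserving", {
  r <- mk_pair(64, 64)
  ps <- extract_patches(r$ortho, r$dsm, r$labels, 32, 32)
  p <- ps[[2]]
  id <- augment_patch(p, rot = 0, shift = c(0, 0))
  expect_identical(id$rgb, p$rgb)
  expect_identical(id$height, p$height)
  r180 <- augment_patch(augment_patch(p, rot = 180, shift = c(0, 0)),
                        rot = 180, shift = c(0, 0))
  expect_identical(r180$height, p$height)
  expect_identical(r180$label, p$label)
  for (rot in c(90, 180, 270)) {
    a <- augment_patch(p, rot = rot, shift = c(0, 0))
    expect_equal(table(a$label), table(p$label))
    expect_equal(sort(as.vector(a$height)), sort(as.vector(p$height)))
  }
  # translation requires source rasters and applies the same crop to channels
  tr <- augment_patch(p, rot = 0, shift = c(5, -3), ortho = r$ortho,
                      dsm = r$dsm, labels = r$labels)
  o <- tr$origin
  expect_identical(tr$height, r$dsm$data[(o[1] + 1):(o[1] + 32),
                                         (o[2] + 1):(o[2] + 32)])
  expect_error(augment_patch(p, rot = 0, shift = c(1, 0)), "source rasters")
  expect_error(augment_patch(p, rot = 45, shift = c(0, 0)), "multiple of 90")
})

test_that("k-fold splits partition the patches with near-equal sizes", {
  ps <- vector("list", 10)
  fs <- kfold_split(ps, 5, seed = 3)
  expect_equal(sort(unique(fs$fold)), 1:5)
  expect_true(all(table(fs$fold) == 2))
  fs2 <- kfold_split(ps, 5, seed = 3)
  expect_identical(fs$fold, fs2$fold)
  fs3 <- kfold_split(vector("list", 11), 3, seed = 1)
  expect_true(max(table(fs3$fold)) - min(table(fs3$fold)) <= 1)
  expect_error(kfold_split(vector("list", 3), 5), "split error")
})

test_that("stitching averages overlapping probabilities then argmaxes", {
  # hand case: overlapping probabilities (0.6,0.4,0) and (0.2,0.8,0) -> class 1
  p1 <- array(rep(c(0.6, 0.4, 0), each = 4), c(2, 2, 3))
  p2 <- array(rep(c(0.2, 0.8, 0), each = 4), c(2, 2, 3))
  st <- stitch_predictions(list(list(origin = c(0, 0), probs = p1),
                                list(origin = c(0, 0), probs = p2)),
                           extent = c(2, 2))
  expect_true(all(st$label$data == 1))
  expect_equal(st$prob[1, 1, ], c(0.4, 0.6, 0))
  # averaging idempotence: duplicated patch equals single patch
  single <- stitch_predictions(list(list(origin = c(0, 0), probs = p1)),
                               extent = c(2, 2))
  dup <- stitch_predictions(list(list(origin = c(0, 0), probs = p1),
                                 list(origin = c(0, 0), probs = p1)),
                            extent = c(2, 2))
  expect_equal(dup$label$data, single$label$data)
  expect_equal(dup$prob, single$prob)
  # uncovered cells are nodata; ties break toward the lower class id
  part <- stitch_predictions(list(list(origin = c(0, 0), probs = p1)),
                             extent = c(4, 4))
  expect_true(all(is.na(part$label$data[3:4, ])))
  tie <- array(1 / 3, c(1, 1, 3))
  stt <- stitch_predictions(list(list(origin = c(0, 0), probs = tie)),
                            extent = c(1, 1))
  expect_equal(stt$label$data[1, 1], 0)
  expect_error(stitch_predictions(list(), c(2, 2)), "stitch error")
})

test_that("tiling then stitching one-hot ground truth reproduces it", {
  r <- mk_pair(96, 96, seed = 4)
  ps <- extract_patches(r$ortho, r$dsm, r$labels, 48, 24)
  preds <- lapply(ps, function(p) {
    oh <- array(0, c(48, 48, 3))
    for (k in 0:2) oh[, , k + 1] <- (p$label == k) * 1
    list(origin = p$origin, probs = oh)
  })
  st <- stitch_predictions(preds, c(96, 96), template = r$dsm)
  expect_equal(st$label$data, r$labels$data)
  expect_true(assert_coregistered(st$label, r$labels))
})
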
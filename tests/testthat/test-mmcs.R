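test_that("shape-aware convolution with unit weights equals vanilla convolution", {
  set.seed(1)
  for (rep in 1:3) {
    x <- array(rnorm(9 * 9 * 2), c(9, 9, 2))
    k <- array(rnorm(3 * 3 * 2 * 5), c(3, 3, 2, 5))
    expect_lt(max(abs(shape_conv_forward(x, k) - conv_forward(x, k))), 1e-5)
  }
})

test_that("constant input zeroes the shape component; output tracks w_base", {
  k <- array(1, c(3, 3, 1, 1))
  x <- matrix(4.2, 6, 6)
  set.seed(2)
  out1 <- shape_conv_forward(x, k, w_base = 2, w_shape = rnorm(9), pad = 0)
  out2 <- shape_conv_forward(x, k, w_base = 2, w_shape = rnorm(9), pad = 0)
  expect_equal(out1, out2)                       # w_shape irrelevant
  out_half <- shape_conv_forward(x, k, w_base = 1, w_shape = 1, pad = 0)
  expect_equal(out1, 2 * out_half)               # linear in w_base
})

test_that("shape-aware convolution matches a brute-force window oracle", {
  set.seed(3)
  x <- matrix(rnorm(25), 5, 5)
  k <- array(rnorm(9), c(3, 3, 1, 1))
  wb <- rnorm(1); ws <- rnorm(9)
  out <- shape_conv_forward(x, k, w_base = wb, w_shape = ws, pad = 0)
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    P <- x[i:(i + 2), j:(j + 2)]
    base <- mean(P)
    recombined <- matrix(ws, 3, 3) * (P - base) + wb * base
    oracle[i, j] <- sum(recombined * k[, , 1, 1])
  }
  expect_equal(out[, , 1], oracle, tolerance = 1e-12)
})

test_that("cross-entropy loss matches analytic and hand-computed values", {
  lab <- matrix(sample(0:2, 16, TRUE), 4, 4)
  expect_equal(ce_loss(array(0, c(4, 4, 3)), lab), log(3), tolerance = 1e-9)
  # strong correct logits drive the loss to zero
  strong <- array(0, c(4, 4, 3))
  for (k in 0:2) strong[, , k + 1] <- (lab == k) * 50
  expect_lt(ce_loss(strong, lab), 1e-6)
  # 2-pixel hand case
  lg <- array(0, c(1, 2, 3))
  lg[1, 1, ] <- c(1, 0, 0); lg[1, 2, ] <- c(0, 2, 1)
  lab2 <- matrix(c(0L, 2L), 1, 2)
  p1 <- exp(1) / (exp(1) + 2)
  p2 <- exp(1) / (1 + exp(2) + exp(1))
  expect_equal(ce_loss(lg, lab2), -(log(p1) + log(p2)) / 2, tolerance = 1e-12)
  expect_error(ce_loss(lg, matrix(NA_real_, 1, 2)), "ignored")
})

test_that("soft IoU loss spans [0, 1] with a verified 4-pixel hand case", {
  lab <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  perfect <- array(0, c(2, 2, 2))
  for (k in 0:1) perfect[, , k + 1] <- (lab == k) * 1
  expect_equal(soft_iou_loss(perfect, lab, classes = 0:1), 0)
  disjoint <- perfect[, , 2:1]
  expect_equal(soft_iou_loss(disjoint, lab, classes = 0:1), 1)
  # uniform 0.5 probabilities: per class I = 1, U = 3, loss = 1 - 1/3
  half <- array(0.5, c(2, 2, 2))
  expect_equal(soft_iou_loss(half, lab, classes = 0:1), 1 - 1 / 3,
               tolerance = 1e-12)
})

test_that("hybrid loss composes CE and IoU with weight mu", {
  set.seed(4)
  lg <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  lab <- matrix(sample(0:2, 16, TRUE), 4, 4)
  expect_identical(hybrid_loss(lg, lab, mu = 0), ce_loss(lg, lab))
  iou <- soft_iou_loss(reef3d:::softmax_probs(lg), lab)
  expect_equal(hybrid_loss(lg, lab, mu = 0.4),
               ce_loss(lg, lab) + 0.4 * iou, tolerance = 1e-12)
  # non-negative and monotone non-decreasing in mu
  mus <- c(0, 0.2, 0.4, 0.8, 1.6)
  vals <- vapply(mus, function(m) hybrid_loss(lg, lab, m), 0)
  expect_true(all(vals >= 0))
  expect_true(all(diff(vals) >= 0))
  # perfect prediction vanishes for any mu
  strong <- array(0, c(4, 4, 3))
  for (k in 0:2) strong[, , k + 1] <- (lab == k) * 60
  expect_lt(hybrid_loss(strong, lab, mu = 0.4), 1e-6)
})

test_that("backpropagated gradients match finite differences", {
  cfg <- mmcs_config("tiny")
  m <- build_model(cfg, seed = 3)
  set.seed(9)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  lab <- matrix(sample(0:2, 64, TRUE), 8, 8)
  fw <- reef3d:::mmcs_forward(m$params, x, cfg)
  lg <- reef3d:::hybrid_loss_grad(fw$logits, lab, 0.4)
  bw <- reef3d:::mmcs_backward(m$params, lg$dlogits, fw$cache, cfg)
  loss_at <- function(params) {
    f <- reef3d:::mmcs_forward(params, x, cfg)
    hybrid_loss(f$logits, lab, 0.4)
  }
  eps <- 1e-5
  for (lname in c("stem", "enc3", "aspp_r2", "sep1", "head")) {
    for (pn in intersect(names(m$params[[lname]]), reef3d:::TRAINABLE)) {
      v <- m$params[[lname]][[pn]]
      for (t in 1:3) {
        i <- sample(length(v), 1)
        p2 <- m$params
        p2[[lname]][[pn]][i] <- v[i] + eps
        lp <- loss_at(p2)
        p2[[lname]][[pn]][i] <- v[i] - eps
        lm <- loss_at(p2)
        fd <- (lp - lm) / (2 * eps)
        an <- bw$grads[[lname]][[pn]][i]
        expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-6), 1e-3)
      }
    }
  }
})

test_that("model construction honors the input contract and determinism", {
  m <- build_model(mmcs_config("tiny"), seed = 7)
  x <- array(rnorm(64 * 64 * 4), c(64, 64, 4))
  out <- reef3d:::mmcs_forward(m$params, x, m$config)
  expect_equal(dim(out$logits), c(64, 64, 3))
  expect_true(all(is.finite(out$logits)))
  # Model A accepts 3 channels
  ma <- build_model(mmcs_config("tiny", use_dsm = FALSE), seed = 7)
  x3 <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  outa <- reef3d:::mmcs_forward(ma$params, x3, ma$config)
  expect_equal(dim(outa$logits), c(32, 32, 3))
  expect_equal(ma$params$stem$c_in, 3L)
  # identical seeds give identical parameters
  m2 <- build_model(mmcs_config("tiny"), seed = 7)
  expect_identical(m$params, m2$params)
})

mk_train_patches <- function(n_scenes = 2, seed0 = 50) {
  patches <- list()
  for (sd in seq_len(n_scenes)) {
    s <- generate_scene(scene_params(
      extent_px = c(96, 96), n_colonies = 2,
      colony_radius_range = c(0.012, 0.02),
      colony_height_range = c(0.02, 0.04), seed = seed0 + sd))
    patches <- c(patches, extract_patches(s$ortho, s$dsm, s$labels, 32, 32))
  }
  patches
}

test_that("a zero learning rate leaves parameters unchanged", {
  patches <- mk_train_patches()
  m <- mmcs_fit(patches, mmcs_config("tiny"), epochs = 1, batch_size = 4,
                lr = 0, seed = 2)
  init <- build_model(mmcs_config("tiny"), seed = 2)  # single run reuses the fit seed
  expect_identical(m$params$stem$W, init$params$stem$W)
  expect_identical(m$params$head$W, init$params$head$W)
})

test_that("training is deterministic and records per-epoch validation metrics", {
  patches <- mk_train_patches()
  m1 <- mmcs_fit(patches, mmcs_config("tiny"), epochs = 2, batch_size = 4,
                 seed = 5)
  m2 <- mmcs_fit(patches, mmcs_config("tiny"), epochs = 2, batch_size = 4,
                 seed = 5)
  expect_identical(m1$history$train_loss, m2$history$train_loss)
  expect_identical(m1$params$head$W, m2$params$head$W)
  expect_equal(nrow(m1$history), 2)
  expect_true(all(c("val_mPA", "val_mIoU") %in% names(m1$history)))
})

test_that("cross-validated training runs one fold per validation subset", {
  patches <- mk_train_patches(3)
  folds <- kfold_split(patches, 3, seed = 1)
  m <- mmcs_fit(patches, mmcs_config("tiny"), folds = folds, epochs = 1,
                batch_size = 8, seed = 2)
  expect_equal(nrow(m$fold_results), 3)
  expect_equal(sort(unique(m$history$run)), 1:3)
  expect_equal(m$cv_mIoU, mean(m$fold_results$val_mIoU))
})

test_that("folding shape weights into kernels preserves the network function", {
  patches <- mk_train_patches()
  m <- mmcs_fit(patches, mmcs_config("tiny"), epochs = 2, batch_size = 4,
                seed = 8)
  folded <- fold_shape_weights(m)
  expect_false(folded$config$use_shapeconv)
  set.seed(1)
  x <- array(rnorm(32 * 32 * 4), c(32, 32, 4))
  o1 <- reef3d:::mmcs_forward(m$params, x, m$config)$logits
  o2 <- reef3d:::mmcs_forward(folded$params, x, folded$config)$logits
  expect_equal(o1, o2, tolerance = 1e-10)
})

test_that("scene prediction returns a co-registered mask and probabilities", {
  patches <- mk_train_patches()
  m <- mmcs_fit(patches, mmcs_config("tiny"), epochs = 2, batch_size = 4,
                seed = 6)
  s <- generate_scene(scene_params(extent_px = c(96, 96), n_colonies = 2,
                                   colony_radius_range = c(0.012, 0.02),
                                   seed = 99))
  pr <- predict(m, s$ortho, s$dsm)
  expect_true(assert_coregistered(pr$label, s$dsm))
  expect_true(all(pr$label$data %in% 0:2))
  expect_equal(dim(pr$prob), c(96, 96, 3))
  covered <- !is.na(pr$prob[, , 1])
  sums <- pr$prob[, , 1] + pr$prob[, , 2] + pr$prob[, , 3]
  expect_equal(sums[covered], rep(1, sum(covered)), tolerance = 1e-9)
  # prediction is deterministic
  pr2 <- predict(m, s$ortho, s$dsm)
  expect_identical(pr$label$data, pr2$label$data)
})
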
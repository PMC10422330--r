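#' Configuration of the multi-modal segmentation network
#'
#' An encoder-decoder network in the DeepLabv3+ mold over a 4-channel
#' RGB + height input: a (optionally shape-aware) convolutional backbone,
#' atrous spatial pyramid pooling (ASPP), and a decoder that fuses low-level
#' features through depthwise-separable convolutions. The ablation axes of
#' interest are `use_dsm` (RGB-only "Model A" vs RGB+DSM "Model B") and
#' `use_shapeconv` (vanilla vs shape-aware backbone, "Model B" vs "Model C");
#' the full model additionally trains under the hybrid loss (`mu > 0`).
#'
#' @param preset `"tiny"` (CPU-scale: 4 encoder stages, <= 32 channels) or
#'   `"full"`
#' @param use_dsm include the height channel (input becomes 4 channels)
#' @param use_shapeconv use shape-aware convolutions in the backbone
#' @param mu weight of the soft-IoU term in the hybrid loss (default 0.4;
#'   0 trains with plain cross-entropy)
#' @param n_classes number of output classes (default 3)
#' @param aspp_rates dilation rates of the ASPP branches (preset default)
#' @param iou_foreground_only average the IoU loss over foreground classes
#'   only (default `FALSE`: all classes including background)
#' @return list of class `mmcs_config`
#' @export
mmcs_config <- function(preset = c("tiny", "full"), use_dsm = TRUE,
                        use_shapeconv = TRUE, mu = 0.4, n_classes = 3L,
                        aspp_rates = NULL, iou_foreground_only = FALSE) {
  preset <- match.arg(preset)
  if (mu < 0) stop("mu must be >= 0", call. = FALSE)
  ch <- switch(preset,
    tiny = list(c1 = 8L, c2 = 16L, c3 = 32L, ca = 16L, cd = 24L, cl = 8L,
                cd2 = 24L, rates = c(2L, 4L), n_res = 0L),
    full = list(c1 = 64L, c2 = 128L, c3 = 256L, ca = 128L, cd = 256L,
                cl = 48L, cd2 = 256L, rates = c(6L, 12L, 18L), n_res = 2L))
  if (!is.null(aspp_rates)) ch$rates <- as.integer(aspp_rates)
  structure(c(list(preset = preset, use_dsm = use_dsm,
                   use_shapeconv = use_shapeconv, mu = mu,
                   n_classes = as.integer(n_classes),
                   in_channels = if (use_dsm) 4L else 3L,
                   iou_foreground_only = iou_foreground_only,
                   output_stride = 4L), ch),
            class = "mmcs_config")
}

backbone_init <- function(cfg, K, c_in, c_out, stride = 1L, dil = 1L) {
  if (cfg$use_shapeconv) nn_shapeconv_init(K, c_in, c_out, stride, dil = dil)
  else nn_conv_init(K, c_in, c_out, stride, dil = dil)
}

mmcs_init_params <- function(cfg) {
  p <- list()
  p$stem <- backbone_init(cfg, 3L, cfg$in_channels, cfg$c1)
  p$enc2 <- backbone_init(cfg, 3L, cfg$c1, cfg$c2, stride = 2L)
  for (i in seq_len(cfg$n_res))
    p[[sprintf("enc2_res%d", i)]] <- backbone_init(cfg, 3L, cfg$c2, cfg$c2)
  p$enc3 <- backbone_init(cfg, 3L, cfg$c2, cfg$c3, stride = 2L)
  for (i in seq_len(cfg$n_res))
    p[[sprintf("enc3_res%d", i)]] <- backbone_init(cfg, 3L, cfg$c3, cfg$c3)
  p$enc4 <- backbone_init(cfg, 3L, cfg$c3, cfg$c3, dil = 2L)
  p$aspp0 <- nn_conv_init(1L, cfg$c3, cfg$ca)
  for (r in cfg$rates)
    p[[sprintf("aspp_r%d", r)]] <- nn_conv_init(3L, cfg$c3, cfg$ca, dil = r)
  p$aspp_proj <- nn_conv_init(1L, cfg$ca * (1L + length(cfg$rates)), cfg$cd)
  p$lowred <- nn_conv_init(1L, cfg$c2, cfg$cl)
  p$sep1 <- nn_sepconv_init(3L, cfg$cd + cfg$cl, cfg$cd2)
  p$sep2 <- nn_sepconv_init(3L, cfg$cd2, cfg$cd2)
  p$head <- nn_conv_init(1L, cfg$cd2, cfg$n_classes)
  p
}

#' Build an (untrained) segmentation model
#'
#' Initializes all parameters from the given seed (He initialization for
#' kernels; shape/base weights start at 1, so a shape-aware backbone starts
#' exactly equivalent to its vanilla counterpart).
#'
#' @param cfg an [mmcs_config()]
#' @param seed integer seed for the initialization
#' @return object of class `mmcs_net` (untrained)
#' @export
build_model <- function(cfg = mmcs_config(), seed = 1L) {
  stopifnot(inherits(cfg, "mmcs_config"))
  set.seed(seed)
  structure(list(params = mmcs_init_params(cfg), config = cfg,
                 norm = NULL, history = NULL, fold_results = NULL,
                 patch_size = NULL, seed = as.integer(seed),
                 trained = FALSE),
            class = "mmcs_net")
}

layer_fw <- function(pr, x) {
  switch(pr$kind,
         conv = nn_conv_fw(pr, x),
         shapeconv = nn_shapeconv_fw(pr, x),
         sepconv = nn_sepconv_fw(pr, x))
}

layer_bw <- function(pr, dy, cache) {
  switch(pr$kind,
         conv = nn_conv_bw(pr, dy, cache),
         shapeconv = nn_shapeconv_bw(pr, dy, cache),
         sepconv = nn_sepconv_bw(pr, dy, cache))
}

# forward pass; input H and W must be divisible by 4 (callers pad)
mmcs_forward <- function(params, x, cfg) {
  cc <- new.env(parent = emptyenv())
  run <- function(name, x, relu = TRUE) {
    r <- layer_fw(params[[name]], x)
    assign(name, r$cache, envir = cc)
    y <- r$y
    if (relu) {
      a <- nn_relu_fw(y)
      assign(paste0(name, ".relu"), a$cache, envir = cc)
      y <- a$y
    }
    y
  }
  run_res <- function(name, x) {
    r <- layer_fw(params[[name]], x)
    assign(name, r$cache, envir = cc)
    a <- nn_relu_fw(r$y + x)
    assign(paste0(name, ".relu"), a$cache, envir = cc)
    a$y
  }
  h <- run("stem", x)
  h <- run("enc2", h)
  for (i in seq_len(cfg$n_res)) h <- run_res(sprintf("enc2_res%d", i), h)
  low <- h
  h <- run("enc3", h)
  for (i in seq_len(cfg$n_res)) h <- run_res(sprintf("enc3_res%d", i), h)
  h <- run("enc4", h)
  branches <- c(list(run("aspp0", h)),
                lapply(cfg$rates, function(r) run(sprintf("aspp_r%d", r), h)))
  asppcat <- array(unlist(branches), c(dim(branches[[1]])[1:2],
                                       cfg$ca * length(branches)))
  h <- run("aspp_proj", asppcat)
  h <- nn_upnn_fw(h, 2L)
  lowr <- run("lowred", low)
  dec <- array(c(h, lowr), c(dim(h)[1:2], cfg$cd + cfg$cl))
  d <- run("sep1", dec)
  d <- run("sep2", d)
  logits_half <- run("head", d, relu = FALSE)
  logits <- nn_upnn_fw(logits_half, 2L)
  list(logits = logits, cache = cc)
}

mmcs_backward <- function(params, dlogits, cc, cfg) {
  grads <- list()
  back <- function(name, dy, relu = TRUE) {
    if (relu) dy <- nn_relu_bw(dy, get(paste0(name, ".relu"), envir = cc))
    r <- layer_bw(params[[name]], dy, get(name, envir = cc))
    grads[[name]] <<- r$grads
    r$dx
  }
  back_res <- function(name, dy) {
    dz <- nn_relu_bw(dy, get(paste0(name, ".relu"), envir = cc))
    r <- layer_bw(params[[name]], dz, get(name, envir = cc))
    grads[[name]] <<- r$grads
    r$dx + dz
  }
  dhalf <- nn_upnn_bw(dlogits, 2L)
  dd <- back("head", dhalf, relu = FALSE)
  dd <- back("sep2", dd)
  ddec <- back("sep1", dd)
  dh <- ddec[, , seq_len(cfg$cd), drop = FALSE]
  dlowr <- ddec[, , cfg$cd + seq_len(cfg$cl), drop = FALSE]
  dlow_from_red <- back("lowred", dlowr)
  dproj_in <- nn_upnn_bw(dh, 2L)
  dasppcat <- back("aspp_proj", dproj_in)
  nb <- 1L + length(cfg$rates)
  denc4_out <- 0
  for (bi in seq_len(nb)) {
    nm <- if (bi == 1L) "aspp0" else sprintf("aspp_r%d", cfg$rates[bi - 1L])
    dbr <- dasppcat[, , (bi - 1L) * cfg$ca + seq_len(cfg$ca), drop = FALSE]
    denc4_out <- denc4_out + back(nm, dbr)
  }
  dh <- back("enc4", denc4_out)
  for (i in rev(seq_len(cfg$n_res))) dh <- back_res(sprintf("enc3_res%d", i), dh)
  dlow <- back("enc3", dh) + dlow_from_red
  for (i in rev(seq_len(cfg$n_res))) dlow <- back_res(sprintf("enc2_res%d", i), dlow)
  dh <- back("enc2", dlow)
  dx <- back("stem", dh)
  list(grads = grads, dx = dx)
}

## ---- losses ----

softmax_probs <- function(logits) {
  d <- dim(logits)
  L <- matrix(logits, d[1] * d[2], d[3])
  mx <- L[, 1L]
  for (k in seq_len(d[3])[-1L]) mx <- pmax(mx, L[, k])
  L <- L - mx
  E <- exp(L)
  P <- E / rowSums(E)
  array(P, d)
}

#' Pixel-wise cross-entropy loss
#'
#' Mean over non-ignored pixels of the negative log softmax probability of
#' the true class.
#'
#' @param logits H x W x K array of class logits
#' @param labels H x W matrix of class ids in `0..K-1`; `NA` pixels are
#'   ignored
#' @return scalar loss
#' @export
ce_loss <- function(logits, labels) ce_loss_grad(logits, labels)$loss

ce_loss_grad <- function(logits, labels) {
  d <- dim(logits)
  P <- matrix(softmax_probs(logits), d[1] * d[2], d[3])
  lab <- as.vector(labels)
  valid <- which(!is.na(lab))
  if (length(valid) == 0L)
    stop("undefined-loss error: all pixels ignored", call. = FALSE)
  idx <- cbind(valid, lab[valid] + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-300)))
  G <- matrix(0, d[1] * d[2], d[3])
  G[valid, ] <- P[valid, , drop = FALSE] / length(valid)
  G[idx] <- G[idx] - 1 / length(valid)
  list(loss = loss, dlogits = array(G, d))
}

#' Soft intersection-over-union loss
#'
#' A map-level loss: per class `c`, the soft intersection
#' `I = sum(p_c * y_c)` and union `U = sum(p_c + y_c - p_c * y_c)` over
#' non-ignored pixels give `loss = 1 - mean_c(I/U)` over the class set.
#' Unlike the pixel-wise cross entropy it scores whole regions, placing
#' extra weight on getting the foreground footprints right.
#'
#' @param probs H x W x K array of softmax probabilities
#' @param labels H x W matrix of class ids (`NA` ignored)
#' @param classes class ids averaged over (default all `0..K-1`)
#' @return scalar loss in `[0, 1]`
#' @export
soft_iou_loss <- function(probs, labels, classes = NULL)
  soft_iou_grad(probs, labels, classes)$loss

soft_iou_grad <- function(probs, labels, classes = NULL) {
  d <- dim(probs)
  if (is.null(classes)) classes <- 0:(d[3] - 1L)
  P <- matrix(probs, d[1] * d[2], d[3])
  lab <- as.vector(labels)
  valid <- which(!is.na(lab))
  if (length(valid) == 0L)
    stop("undefined-loss error: empty label map", call. = FALSE)
  G <- matrix(0, d[1] * d[2], d[3])
  total <- 0
  for (k in classes) {
    pc <- P[valid, k + 1L]
    y <- as.numeric(lab[valid] == k)
    I <- sum(pc * y)
    U <- sum(pc + y - pc * y)
    if (U <= 0) { total <- total + 1; next }  # class absent everywhere
    total <- total + I / U
    G[valid, k + 1L] <- -(y * U - I * (1 - y)) / U^2 / length(classes)
  }
  list(loss = 1 - total / length(classes), dprobs = array(G, d))
}

#' Hybrid segmentation loss
#'
#' `L = L_CE + mu * L_IoU`: pixel-wise cross entropy plus a weighted soft
#' IoU term (default weight `mu = 0.4`); `mu = 0` reduces exactly to the
#' cross entropy.
#'
#' @param logits H x W x K class logits
#' @param labels H x W class ids (`NA` ignored)
#' @param mu weight of the IoU term (>= 0)
#' @param classes class set for the IoU term (default all)
#' @return scalar loss
#' @export
hybrid_loss <- function(logits, labels, mu = 0.4, classes = NULL)
  hybrid_loss_grad(logits, labels, mu, classes)$loss

hybrid_loss_grad <- function(logits, labels, mu = 0.4, classes = NULL) {
  ce <- ce_loss_grad(logits, labels)
  if (mu == 0) return(ce)
  d <- dim(logits)
  probs <- softmax_probs(logits)
  iou <- soft_iou_grad(probs, labels, classes)
  # chain rule through the softmax: dL/dz_k = p_k * (g_k - sum_c g_c p_c)
  P <- matrix(probs, d[1] * d[2], d[3])
  G <- matrix(iou$dprobs, d[1] * d[2], d[3])
  dz <- P * (G - rowSums(G * P))
  list(loss = ce$loss + mu * iou$loss,
       dlogits = ce$dlogits + mu * array(dz, d))
}

## ---- normalization ----

rgb_norm_stats <- function(patches) {
  sums <- numeric(3); sqs <- numeric(3); n <- 0
  for (p in patches) {
    v <- p$rgb / 255
    for (ch in 1:3) {
      x <- v[, , ch]
      sums[ch] <- sums[ch] + sum(x, na.rm = TRUE)
      sqs[ch] <- sqs[ch] + sum(x^2, na.rm = TRUE)
    }
    n <- n + sum(!is.na(v[, , 1]))
  }
  mean <- sums / n
  sd <- sqrt(pmax(sqs / n - mean^2, 1e-8))
  list(mean = mean, sd = sd)
}

# height normalization: remove the patch median (absolute depth is
# arbitrary), scale by a fixed 0.05 m so relief amplitude is preserved
# across patches
normalize_patch_input <- function(p, norm, use_dsm) {
  d <- dim(p$height)
  C <- if (use_dsm) 4L else 3L
  x <- array(0, c(d[1], d[2], C))
  for (ch in 1:3) {
    v <- p$rgb[, , ch] / 255
    v <- (v - norm$mean[ch]) / norm$sd[ch]
    v[is.na(v)] <- 0
    x[, , ch] <- v
  }
  if (use_dsm) {
    h <- p$height
    med <- stats::median(h, na.rm = TRUE)
    if (is.na(med)) med <- 0
    h <- (h - med) / 0.05
    h[is.na(h)] <- 0
    x[, , 4] <- h
  }
  x
}

## ---- training ----

eval_patches <- function(params, cfg, xs, labs, n_classes) {
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(xs)) {
    out <- mmcs_forward(params, xs[[i]], cfg)
    d <- dim(out$logits)
    pred <- matrix(max.col(matrix(out$logits, d[1] * d[2], d[3]),
                           ties.method = "first") - 1, d[1], d[2])
    cm <- cm + confusion(pred, labs[[i]], n_classes)
  }
  list(cm = cm, mPA = mean_pixel_accuracy(cm), mIoU = mean_iou(cm))
}

train_one_run <- function(cfg, train_x, train_y, val_x, val_y, epochs,
                          batch_size, lr, seed, verbose, run_id = 1L) {
  set.seed(seed)
  params <- mmcs_init_params(cfg)
  opt <- adam_init(params)
  best <- list(mIoU = -Inf, params = params, mPA = NA_real_, epoch = 0L)
  hist <- NULL
  n <- length(train_x)
  for (e in seq_len(epochs)) {
    lr_t <- lr * 0.5 * (1 + cos(pi * (e - 1) / epochs))
    ord <- sample.int(n)
    losses <- numeric(0)
    for (b0 in seq(1L, n, by = batch_size)) {
      bidx <- ord[b0:min(b0 + batch_size - 1L, n)]
      acc <- NULL
      bl <- 0
      for (i in bidx) {
        fw <- mmcs_forward(params, train_x[[i]], cfg)
        lg <- hybrid_loss_grad(fw$logits, train_y[[i]], cfg$mu,
                               if (cfg$iou_foreground_only) 1:(cfg$n_classes - 1L)
                               else NULL)
        bl <- bl + lg$loss
        bw <- mmcs_backward(params, lg$dlogits, fw$cache, cfg)
        acc <- if (is.null(acc)) bw$grads else grads_accumulate(acc, bw$grads)
      }
      if (!is.finite(bl))
        stop(sprintf("training error: divergent loss at epoch %d", e),
             call. = FALSE)
      acc <- grads_scale(acc, 1 / length(bidx))
      st <- adam_step(params, acc, opt, lr_t)
      params <- st$params; opt <- st$state
      losses <- c(losses, bl / length(bidx))
    }
    ev <- eval_patches(params, cfg, val_x, val_y, cfg$n_classes)
    hist <- rbind(hist, data.frame(run = run_id, epoch = e,
                                   lr = lr_t,
                                   train_loss = mean(losses),
                                   val_mPA = ev$mPA, val_mIoU = ev$mIoU))
    if (ev$mIoU > best$mIoU)
      best <- list(mIoU = ev$mIoU, mPA = ev$mPA, params = params, epoch = e)
    if (verbose)
      message(sprintf("run %d epoch %d: loss %.4f, val mPA %.3f, mIoU %.3f",
                      run_id, e, mean(losses), ev$mPA, ev$mIoU))
  }
  list(best = best, history = hist)
}

#' Fit the segmentation network
#'
#' Trains the network on labeled patches with Adam under a cosine learning
#' rate decay, tracking validation mPA/mIoU per epoch and keeping the
#' best-validation parameters. With a [kfold_split()] the model is trained
#' once per fold (each fold serving once as the validation set) and the
#' returned object carries per-fold histories, averaged metrics, and the
#' parameters of the best-performing fold; without folds a single random
#' validation split of `val_fraction` is used.
#'
#' @param patches list of patch records from [extract_patches()] (labels
#'   required)
#' @param config an [mmcs_config()]
#' @param folds optional [kfold_split()] of the patches
#' @param epochs training epochs per run (default 30)
#' @param batch_size minibatch size (default 8)
#' @param lr peak Adam learning rate (default 1e-3)
#' @param val_fraction validation fraction when `folds` is `NULL`
#' @param seed integer seed controlling initialization, shuffling and the
#'   validation split
#' @param verbose print per-epoch progress
#' @return object of class `mmcs_net` with `params` (best), `history`,
#'   `fold_results`, `cv_mPA`/`cv_mIoU` (averages over runs)
#' @export
mmcs_fit <- function(patches, config = mmcs_config(), folds = NULL,
                     epochs = 30L, batch_size = 8L, lr = 1e-3,
                     val_fraction = 0.2, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(config, "mmcs_config"), length(patches) >= 2L)
  if (any(vapply(patches, function(p) is.null(p$label), TRUE)))
    stop("all training patches need labels", call. = FALSE)
  set.seed(seed)
  norm <- rgb_norm_stats(patches)
  xs <- lapply(patches, normalize_patch_input, norm = norm,
               use_dsm = config$use_dsm)
  ys <- lapply(patches, `[[`, "label")
  assign_runs <- if (!is.null(folds)) {
    stopifnot(inherits(folds, "fold_spec"),
              length(folds$fold) == length(patches))
    lapply(seq_len(folds$n_folds), function(k) which(folds$fold == k))
  } else {
    nv <- max(1L, round(val_fraction * length(patches)))
    list(sample.int(length(patches), nv))
  }
  runs <- list(); hist <- NULL
  for (k in seq_along(assign_runs)) {
    val_idx <- assign_runs[[k]]
    tr_idx <- setdiff(seq_along(patches), val_idx)
    if (length(tr_idx) == 0L)
      stop("training error: no training patches left for run ", k, call. = FALSE)
    r <- train_one_run(config, xs[tr_idx], ys[tr_idx], xs[val_idx], ys[val_idx],
                       epochs, batch_size, lr, seed + k - 1L, verbose, k)
    runs[[k]] <- r$best
    hist <- rbind(hist, r$history)
  }
  mious <- vapply(runs, `[[`, 0, "mIoU")
  best_run <- which.max(mious)
  structure(list(params = runs[[best_run]]$params, config = config,
                 norm = norm, history = hist,
                 fold_results = data.frame(
                   run = seq_along(runs),
                   best_epoch = vapply(runs, `[[`, 0L, "epoch"),
                   val_mPA = vapply(runs, `[[`, 0, "mPA"),
                   val_mIoU = mious),
                 cv_mPA = mean(vapply(runs, `[[`, 0, "mPA")),
                 cv_mIoU = mean(mious),
                 patch_size = nrow(patches[[1]]$height),
                 seed = as.integer(seed), trained = TRUE),
            class = "mmcs_net")
}

#' @export
print.mmcs_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<mmcs_net: %s preset, %d-channel input%s%s, mu = %g%s>\n",
              cfg$preset, cfg$in_channels,
              if (cfg$use_shapeconv) ", shape-aware backbone" else "",
              if (cfg$use_dsm) " (RGB+DSM)" else " (RGB only)",
              cfg$mu, if (x$trained) "" else ", untrained"))
  if (x$trained)
    cat(sprintf("  runs: %d; mean val mPA %.3f, mIoU %.3f\n",
                nrow(x$fold_results), x$cv_mPA, x$cv_mIoU))
  invisible(x)
}

#' @export
summary.mmcs_net <- function(object, ...) {
  cat("Segmentation network\n")
  print(object)
  np <- 0
  for (l in object$params) for (p in intersect(names(l), TRAINABLE))
    np <- np + length(l[[p]])
  cat(sprintf("  trainable parameters: %d\n", np))
  if (object$trained) {
    cat("  per-run best validation metrics:\n")
    print(object$fold_results, row.names = FALSE)
  }
  invisible(object$fold_results)
}

#' @export
coef.mmcs_net <- function(object, ...) object$params

#' @export
plot.mmcs_net <- function(x, ...) {
  if (is.null(x$history)) stop("untrained model has no history", call. = FALSE)
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(h$epoch, h$train_loss, type = "n", xlab = "epoch",
                 ylab = "training loss", main = "loss")
  for (r in unique(h$run))
    graphics::lines(h$epoch[h$run == r], h$train_loss[h$run == r],
                    col = r)
  graphics::plot(h$epoch, h$val_mIoU, type = "n", xlab = "epoch",
                 ylab = "validation mIoU", ylim = c(0, 1), main = "mIoU")
  for (r in unique(h$run))
    graphics::lines(h$epoch[h$run == r], h$val_mIoU[h$run == r], col = r)
  invisible(x)
}

pad_to_multiple <- function(x, m) {
  d <- dim(x)
  ph <- (m - d[1] %% m) %% m
  pw <- (m - d[2] %% m) %% m
  if (ph == 0 && pw == 0) return(list(x = x, ph = 0L, pw = 0L))
  out <- array(0, c(d[1] + ph, d[2] + pw, d[3]))
  out[seq_len(d[1]), seq_len(d[2]), ] <- x
  # replicate edges rather than zero-fill
  if (ph > 0) out[d[1] + seq_len(ph), seq_len(d[2]), ] <-
    out[rep(d[1], ph), seq_len(d[2]), , drop = FALSE]
  if (pw > 0) out[, d[2] + seq_len(pw), ] <-
    out[, rep(d[2], pw), , drop = FALSE]
  list(x = out, ph = ph, pw = pw)
}

predict_patch_probs <- function(model, p) {
  x <- normalize_patch_input(p, model$norm, model$config$use_dsm)
  pad <- pad_to_multiple(x, model$config$output_stride)
  out <- mmcs_forward(model$params, pad$x, model$config)
  lg <- out$logits
  d0 <- dim(x)
  softmax_probs(lg[seq_len(d0[1]), seq_len(d0[2]), , drop = FALSE])
}

#' Predict a full-scene segmentation
#'
#' Tiles the scene, normalizes each patch with the model's stored
#' statistics, forwards, and stitches the per-patch class probabilities back
#' to a full-scene mask (overlaps averaged, argmax, ties toward the lower
#' class id). The output rasters are co-registered with the input.
#'
#' @param object a trained `mmcs_net`
#' @param ortho rgb [reef_raster()]
#' @param dsm co-registered height raster (required when the model uses the
#'   height channel)
#' @param window patch size (default: training patch size, clipped to the
#'   scene)
#' @param stride tiling stride (default `window / 2`)
#' @param ... unused
#' @return list with `label` (label [reef_raster()]) and `prob`
#'   (rows x cols x K probability array)
#' @export
predict.mmcs_net <- function(object, ortho, dsm = NULL, window = NULL,
                             stride = NULL, ...) {
  if (!object$trained) stop("model is untrained", call. = FALSE)
  cfg <- object$config
  if (cfg$use_dsm && is.null(dsm))
    stop("model uses the height channel; dsm is required", call. = FALSE)
  if (is.null(dsm)) {
    dsm <- reef_raster(matrix(0, dim(ortho$data)[1], dim(ortho$data)[2]),
                       c(ortho$x_origin, ortho$y_origin), ortho$cell, "height")
  }
  assert_coregistered(ortho, dsm)
  d <- dim(dsm$data)
  if (is.null(window)) window <- min(object$patch_size, d[1], d[2])
  window <- (window %/% cfg$output_stride) * cfg$output_stride
  if (is.null(stride)) stride <- max(window %/% 2L, 1L)
  patches <- extract_patches(ortho, dsm, NULL, window, stride,
                             max_nodata_frac = 1)
  preds <- lapply(patches, function(p)
    list(origin = p$origin, probs = predict_patch_probs(object, p)))
  stitch_predictions(preds, d[1:2], template = dsm)
}

#' Fold shape-aware weights into plain convolutions
#'
#' The shape/base recombination is linear in the unfolded input window, so
#' after training the learnable shape weights can be absorbed into the
#' convolution kernel; inference then costs exactly the same as a vanilla
#' network. Returns a model whose backbone layers are ordinary convolutions
#' with identical outputs.
#'
#' @param model an `mmcs_net` with a shape-aware backbone
#' @return an equivalent `mmcs_net` with `use_shapeconv = FALSE`
#' @export
fold_shape_weights <- function(model) {
  stopifnot(inherits(model, "mmcs_net"))
  for (nm in names(model$params)) {
    pr <- model$params[[nm]]
    if (pr$kind != "shapeconv") next
    K2 <- pr$K^2
    n <- K2 * pr$c_in
    M <- diag(pr$w_shape, n)
    for (c in seq_len(pr$c_in)) {
      blk <- (c - 1L) * K2 + seq_len(K2)
      M[blk, blk] <- M[blk, blk] +
        (pr$w_base[c] - pr$w_shape[blk]) %o% rep(1 / K2, K2)
    }
    pr$W <- pr$W %*% M
    pr$w_base <- NULL; pr$w_shape <- NULL
    pr$kind <- "conv"
    model$params[[nm]] <- pr
  }
  model$config$use_shapeconv <- FALSE
  model
}
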
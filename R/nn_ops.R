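# Differentiable layer primitives for the segmentation network.
#
# Feature maps are H x W x C arrays; convolutions run as im2col (C++) plus
# BLAS matrix products. Every *_fw returns list(y, cache); every *_bw takes
# the upstream gradient and the cache and returns list(dx, grads).

conv_out_extent <- function(n, K, stride, pad, dil) {
  (n + 2L * pad - ((K - 1L) * dil + 1L)) %/% stride + 1L
}

as_cube <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

# ---- vanilla convolution ----

nn_conv_init <- function(K, c_in, c_out, stride = 1L, pad = NULL, dil = 1L) {
  if (is.null(pad)) pad <- if (K == 1L) 0L else dil * ((K - 1L) %/% 2L)
  sdv <- sqrt(2 / (K * K * c_in))
  list(W = matrix(stats::rnorm(c_out * K * K * c_in, 0, sdv), c_out),
       b = numeric(c_out),
       K = K, c_in = c_in, c_out = c_out, stride = as.integer(stride),
       pad = as.integer(pad), dil = as.integer(dil), kind = "conv")
}

nn_conv_fw <- function(pr, x) {
  x <- as_cube(x)
  H <- dim(x)[1]; W <- dim(x)[2]
  cols <- im2col_cpp(x, pr$K, pr$stride, pr$pad, pr$dil)
  out <- pr$W %*% cols + pr$b
  Ho <- conv_out_extent(H, pr$K, pr$stride, pr$pad, pr$dil)
  Wo <- conv_out_extent(W, pr$K, pr$stride, pr$pad, pr$dil)
  y <- array(t(out), c(Ho, Wo, pr$c_out))
  list(y = y, cache = list(cols = cols, H = H, W = W))
}

nn_conv_bw <- function(pr, dy, cache) {
  Ho <- dim(dy)[1]; Wo <- dim(dy)[2]
  dY <- t(matrix(dy, Ho * Wo, pr$c_out))
  dW <- dY %*% t(cache$cols)
  db <- rowSums(dY)
  dcols <- crossprod(pr$W, dY)
  dx <- col2im_cpp(dcols, cache$H, cache$W, pr$c_in, pr$K, pr$stride,
                   pr$pad, pr$dil)
  list(dx = dx, grads = list(W = dW, b = db))
}

# ---- shape-aware convolution ----
# Each K x K window is split per input channel into its spatial mean (base)
# and the residual (shape); both are reweighted by learnable weights
# (w_base: one per channel, w_shape: one per kernel position and channel)
# and recombined before the ordinary convolution. With all weights at 1 the
# layer reduces exactly to the vanilla convolution.

nn_shapeconv_init <- function(K, c_in, c_out, stride = 1L, pad = NULL, dil = 1L) {
  pr <- nn_conv_init(K, c_in, c_out, stride, pad, dil)
  pr$w_base <- rep(1, c_in)
  pr$w_shape <- rep(1, K * K * c_in)
  pr$kind <- "shapeconv"
  pr
}

shapeconv_recombine <- function(pr, cols) {
  K2 <- pr$K^2
  P <- ncol(cols)
  m <- matrix(.colMeans(cols, K2, pr$c_in * P), pr$c_in, P)
  base <- m[rep(seq_len(pr$c_in), each = K2), , drop = FALSE]
  wb <- rep(pr$w_base, each = K2)
  cols2 <- pr$w_shape * (cols - base) + wb * base
  list(cols2 = cols2, base = base)
}

nn_shapeconv_fw <- function(pr, x) {
  x <- as_cube(x)
  H <- dim(x)[1]; W <- dim(x)[2]
  cols <- im2col_cpp(x, pr$K, pr$stride, pr$pad, pr$dil)
  rc <- shapeconv_recombine(pr, cols)
  out <- pr$W %*% rc$cols2 + pr$b
  Ho <- conv_out_extent(H, pr$K, pr$stride, pr$pad, pr$dil)
  Wo <- conv_out_extent(W, pr$K, pr$stride, pr$pad, pr$dil)
  list(y = array(t(out), c(Ho, Wo, pr$c_out)),
       cache = list(cols = cols, cols2 = rc$cols2, base = rc$base,
                    H = H, W = W))
}

nn_shapeconv_bw <- function(pr, dy, cache) {
  K2 <- pr$K^2
  Ho <- dim(dy)[1]; Wo <- dim(dy)[2]
  P <- Ho * Wo
  dY <- t(matrix(dy, P, pr$c_out))
  dW <- dY %*% t(cache$cols2)
  db <- rowSums(dY)
  dcols2 <- crossprod(pr$W, dY)
  shp <- cache$cols - cache$base
  dw_shape <- rowSums(dcols2 * shp)
  tmp <- dcols2 * cache$base
  dw_base <- colSums(matrix(rowSums(tmp), K2, pr$c_in))
  wb <- rep(pr$w_base, each = K2)
  t2 <- (wb - pr$w_shape) * dcols2
  tm <- matrix(.colMeans(t2, K2, pr$c_in * P), pr$c_in, P)
  dcols <- pr$w_shape * dcols2 + tm[rep(seq_len(pr$c_in), each = K2), , drop = FALSE]
  dx <- col2im_cpp(dcols, cache$H, cache$W, pr$c_in, pr$K, pr$stride,
                   pr$pad, pr$dil)
  list(dx = dx, grads = list(W = dW, b = db, w_base = dw_base,
                             w_shape = dw_shape))
}

# ---- depthwise-separable convolution (decoder) ----

nn_sepconv_init <- function(K, c_in, c_out) {
  list(Wd = matrix(stats::rnorm(c_in * K * K, 0, sqrt(2 / (K * K))), c_in),
       Wp = matrix(stats::rnorm(c_out * c_in, 0, sqrt(2 / c_in)), c_out),
       b = numeric(c_out),
       K = K, c_in = c_in, c_out = c_out,
       stride = 1L, pad = (K - 1L) %/% 2L, dil = 1L, kind = "sepconv")
}

nn_sepconv_fw <- function(pr, x) {
  x <- as_cube(x)
  H <- dim(x)[1]; W <- dim(x)[2]
  K2 <- pr$K^2
  cols <- im2col_cpp(x, pr$K, 1L, pr$pad, 1L)
  P <- ncol(cols)
  wvec <- as.vector(t(pr$Wd))                   # K2*c_in, channel blocks
  dwout <- matrix(.colSums(wvec * cols, K2, pr$c_in * P), pr$c_in, P)
  out <- pr$Wp %*% dwout + pr$b
  list(y = array(t(out), c(H, W, pr$c_out)),
       cache = list(cols = cols, dwout = dwout, H = H, W = W))
}

nn_sepconv_bw <- function(pr, dy, cache) {
  K2 <- pr$K^2
  P <- ncol(cache$cols)
  dY <- t(matrix(dy, P, pr$c_out))
  db <- rowSums(dY)
  dWp <- dY %*% t(cache$dwout)
  ddw <- crossprod(pr$Wp, dY)                   # c_in x P
  ddw_exp <- ddw[rep(seq_len(pr$c_in), each = K2), , drop = FALSE]
  dWd <- t(matrix(rowSums(ddw_exp * cache$cols), K2, pr$c_in))
  wvec <- as.vector(t(pr$Wd))
  dcols <- ddw_exp * wvec
  dx <- col2im_cpp(dcols, cache$H, cache$W, pr$c_in, pr$K, 1L, pr$pad, 1L)
  list(dx = dx, grads = list(Wd = dWd, Wp = dWp, b = db))
}

# ---- activation / resampling ----

nn_relu_fw <- function(x) list(y = pmax(x, 0), cache = x > 0)
nn_relu_bw <- function(dy, cache) dy * cache

nn_upnn_fw <- function(x, f) {
  x <- as_cube(x)
  H <- dim(x)[1]; W <- dim(x)[2]
  x[rep(seq_len(H), each = f), rep(seq_len(W), each = f), , drop = FALSE]
}

nn_upnn_bw <- function(dy, f) {
  H <- dim(dy)[1] %/% f; W <- dim(dy)[2] %/% f; C <- dim(dy)[3]
  out <- array(0, c(H, W, C))
  gr <- rep(seq_len(H), each = f); gc <- rep(seq_len(W), each = f)
  for (ch in seq_len(C)) {
    m <- rowsum(dy[, , ch], gr)
    out[, , ch] <- t(rowsum(t(m), gc))
  }
  out
}

# ---- parameter tree utilities ----

TRAINABLE <- c("W", "b", "Wd", "Wp", "w_base", "w_shape")

param_walk <- function(params, f) {
  for (lname in names(params)) {
    for (p in intersect(names(params[[lname]]), TRAINABLE)) {
      params[[lname]][[p]] <- f(params[[lname]][[p]], lname, p)
    }
  }
  params
}

zero_like <- function(params) param_walk(params, function(v, l, p) v * 0)

grads_accumulate <- function(acc, g) {
  for (lname in names(g)) for (p in names(g[[lname]]))
    acc[[lname]][[p]] <- acc[[lname]][[p]] + g[[lname]][[p]]
  acc
}

grads_scale <- function(g, s) param_walk(g, function(v, l, p) v * s)

adam_init <- function(params)
  list(m = zero_like(params), v = zero_like(params), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (lname in names(params)) {
    for (p in intersect(names(params[[lname]]), TRAINABLE)) {
      g <- grads[[lname]][[p]]
      state$m[[lname]][[p]] <- beta1 * state$m[[lname]][[p]] + (1 - beta1) * g
      state$v[[lname]][[p]] <- beta2 * state$v[[lname]][[p]] + (1 - beta2) * g^2
      mh <- state$m[[lname]][[p]] / bc1
      vh <- state$v[[lname]][[p]] / bc2
      params[[lname]][[p]] <- params[[lname]][[p]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(params = params, state = state)
}

## ---- exported functional layer interfaces ----

kernel_to_mat <- function(kernel) {
  d <- dim(kernel)
  if (length(d) != 4L) stop("kernel must be K x K x C_in x C_out", call. = FALSE)
  if (d[1] != d[2]) stop("kernel must be square", call. = FALSE)
  t(matrix(kernel, d[1] * d[2] * d[3], d[4]))
}

#' Plain 2D convolution of a feature grid
#'
#' Reference forward convolution used as the degenerate case of the
#' shape-aware layer.
#'
#' @param x H x W x C_in array (a matrix is treated as one channel)
#' @param kernel K x K x C_in x C_out array
#' @param bias per-output-channel bias (default 0)
#' @param stride,dilation integers
#' @param pad padding in cells (default keeps size for stride 1)
#' @return Ho x Wo x C_out array
#' @export
conv_forward <- function(x, kernel, bias = 0, stride = 1L, dilation = 1L,
                         pad = NULL) {
  x <- as_cube(x)
  d <- dim(kernel)
  if (dim(x)[3] != d[3]) stop("dimension error: channel mismatch", call. = FALSE)
  pr <- list(W = kernel_to_mat(kernel), b = rep(bias, length.out = d[4]),
             K = d[1], c_in = d[3], c_out = d[4], stride = as.integer(stride),
             pad = if (is.null(pad)) as.integer(dilation) * ((d[1] - 1L) %/% 2L)
                   else as.integer(pad),
             dil = as.integer(dilation), kind = "conv")
  nn_conv_fw(pr, x)$y
}

#' Shape-aware 2D convolution of a feature grid
#'
#' Each K x K input window is decomposed per channel into its spatial mean
#' (the base component) and the residual around it (the shape component);
#' the two are reweighted by the learnable `w_base` (one weight per input
#' channel) and `w_shape` (one per kernel position and channel), recombined,
#' and convolved with `kernel`. With `w_base = w_shape = 1` the output
#' equals [conv_forward()] exactly, and after training the weights can be
#' folded into the kernel (see [fold_shape_weights()]), so inference costs
#' nothing extra.
#'
#' @inheritParams conv_forward
#' @param w_base numeric, recycled to `C_in`
#' @param w_shape numeric, recycled to `K * K * C_in`
#' @return Ho x Wo x C_out array
#' @export
shape_conv_forward <- function(x, kernel, w_base = 1, w_shape = 1, bias = 0,
                               stride = 1L, dilation = 1L, pad = NULL) {
  x <- as_cube(x)
  d <- dim(kernel)
  if (dim(x)[3] != d[3]) stop("dimension error: channel mismatch", call. = FALSE)
  pr <- list(W = kernel_to_mat(kernel), b = rep(bias, length.out = d[4]),
             w_base = rep(w_base, length.out = d[3]),
             w_shape = rep(w_shape, length.out = d[1] * d[2] * d[3]),
             K = d[1], c_in = d[3], c_out = d[4], stride = as.integer(stride),
             pad = if (is.null(pad)) as.integer(dilation) * ((d[1] - 1L) %/% 2L)
                   else as.integer(pad),
             dil = as.integer(dilation), kind = "shapeconv")
  nn_shapeconv_fw(pr, x)$y
}
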
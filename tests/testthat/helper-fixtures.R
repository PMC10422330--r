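# Small deterministic fixtures shared across tests.

tiny_scene <- function(seed = 11, extent = 256L, n = 6L) {
  generate_scene(scene_params(
    extent_px = c(extent, extent), n_colonies = n,
    colony_radius_range = c(0.025, 0.04) * extent / 256,
    colony_height_range = c(0.03, 0.06), seed = seed))
}

random_height_raster <- function(H, W, seed = 1, cell = 0.001, scale = 0.01) {
  set.seed(seed)
  reef_raster(matrix(rnorm(H * W, 0, scale), H, W), cell = cell,
              meaning = "height")
}

# independent Horn-stencil slope/aspect oracle (plain loops)
horn_oracle <- function(z, cell) {
  H <- nrow(z); W <- ncol(z)
  slope <- aspect <- matrix(NA_real_, H, W)
  for (r in 2:(H - 1)) for (c in 2:(W - 1)) {
    n <- z[r - 1, c]; s <- z[r + 1, c]; e <- z[r, c + 1]; w <- z[r, c - 1]
    ne <- z[r - 1, c + 1]; nw <- z[r - 1, c - 1]
    se <- z[r + 1, c + 1]; sw <- z[r + 1, c - 1]
    if (any(is.na(c(n, s, e, w, ne, nw, se, sw, z[r, c])))) next
    p <- ((ne + 2 * e + se) - (nw + 2 * w + sw)) / (8 * cell)
    q <- ((nw + 2 * n + ne) - (sw + 2 * s + se)) / (8 * cell)
    slope[r, c] <- atan(sqrt(p^2 + q^2))
    aspect[r, c] <- if (p == 0 && q == 0) 0 else atan2(-p, -q) %% (2 * pi)
  }
  list(slope = slope, aspect = aspect)
}

# independent triple-loop VRM oracle built on the Horn oracle
vrm_oracle <- function(z, cell, w) {
  sa <- horn_oracle(z, cell)
  nx <- sin(sa$slope) * sin(sa$aspect)
  ny <- sin(sa$slope) * cos(sa$aspect)
  nz <- cos(sa$slope)
  H <- nrow(z); W <- ncol(z)
  h <- (w - 1) %/% 2
  out <- matrix(NA_real_, H, W)
  for (r in (h + 1):(H - h)) for (c in (h + 1):(W - h)) {
    rs <- (r - h):(r + h); cs <- (c - h):(c + h)
    if (any(is.na(nx[rs, cs]))) next
    R <- sqrt(sum(nx[rs, cs])^2 + sum(ny[rs, cs])^2 + sum(nz[rs, cs])^2)
    out[r, c] <- 1 - R / w^2
  }
  out
}

# brute-force per-point roughness oracle: O(N^2) neighbor scan + eigen fit
roughness_oracle <- function(xyz, radius) {
  n <- nrow(xyz)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 <= radius^2 & seq_len(n) != i)
    if (length(nb) < 3) next
    P <- xyz[nb, , drop = FALSE]
    cen <- colMeans(P)
    cv <- crossprod(sweep(P, 2, cen)) / nrow(P)
    e <- eigen(cv, symmetric = TRUE)
    if (e$values[1] <= 0 || e$values[2] <= 1e-12 * e$values[1]) next
    out[i] <- abs(sum((xyz[i, ] - cen) * e$vectors[, 3]))
  }
  out
}
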
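#' Extract aligned training/inference patches from co-registered rasters
#'
#' Slides a `window x window` box at multiples of `stride` over the scene
#' (origins 0-based; count per axis = `floor((extent - window)/stride) + 1`)
#' and cuts aligned RGB, height and (optionally) label patches. Patches whose
#' height channel has more than `max_nodata_frac` nodata cells are dropped.
#'
#' @param ortho rgb [reef_raster()]
#' @param dsm co-registered height raster
#' @param labels optional co-registered label raster
#' @param window patch size in cells (default 448)
#' @param stride step in cells (default 224)
#' @param max_nodata_frac drop threshold on the nodata fraction (default 0.5)
#' @return list of patch records: `rgb` (window x window x 3), `height`,
#'   `label` (or `NULL`), `origin` (0-based `c(row, col)` offset)
#' @export
extract_patches <- function(ortho, dsm, labels = NULL, window = 448L,
                            stride = 224L, max_nodata_frac = 0.5) {
  assert_coregistered(ortho, dsm)
  if (!is.null(labels)) assert_coregistered(dsm, labels)
  window <- as.integer(window); stride <- as.integer(stride)
  H <- nrow(dsm$data); W <- ncol(dsm$data)
  if (window > H || window > W)
    stop("tiling error: extent smaller than window", call. = FALSE)
  or <- seq(0L, H - window, by = stride)
  oc <- seq(0L, W - window, by = stride)
  out <- list()
  for (r0 in or) for (c0 in oc) {
    ri <- (r0 + 1L):(r0 + window); ci <- (c0 + 1L):(c0 + window)
    h <- dsm$data[ri, ci]
    if (mean(is.na(h)) > max_nodata_frac) next
    out[[length(out) + 1L]] <- list(
      rgb = ortho$data[ri, ci, , drop = FALSE],
      height = h,
      label = if (!is.null(labels)) labels$data[ri, ci] else NULL,
      origin = c(r0, c0))
  }
  out
}

rot90cw <- function(m) t(m[nrow(m):1L, , drop = FALSE])

rot_k90 <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  if (is.matrix(m)) {
    for (i in seq_len(k)) m <- rot90cw(m)
    return(m)
  }
  out <- m
  for (ch in seq_len(dim(m)[3])) {
    p <- m[, , ch]
    for (i in seq_len(k)) p <- rot90cw(p)
    if (ch == 1L) out <- array(0, c(dim(p), dim(m)[3]))
    out[, , ch] <- p
  }
  out
}

#' Augment a patch by rotation and (optionally) translation
#'
#' Applies the identical geometric transform to RGB, height and label
#' channels. Rotations are multiples of 90 degrees, so no channel is ever
#' interpolated; labels stay categorical. Translation is realized as a
#' jittered re-crop from the source rasters and therefore requires them: when
#' `ortho`/`dsm`/`labels` are omitted, only the rotation is applied.
#'
#' @param p a patch record from [extract_patches()]
#' @param seed optional seed; draws `rot` from \{0, 90, 180, 270\} and the
#'   crop jitter from `[-max_shift, max_shift]` when those are `NULL`
#' @param rot rotation in degrees (multiple of 90), or `NULL` to draw
#' @param shift integer `c(drow, dcol)` crop offset, or `NULL` to draw
#' @param ortho,dsm,labels source rasters enabling translation
#' @param max_shift jitter bound in cells (default `stride/2` for the
#'   standard 224 stride)
#' @return an augmented patch record (origin updated if translated)
#' @export
augment_patch <- function(p, seed = NULL, rot = NULL, shift = NULL,
                          ortho = NULL, dsm = NULL, labels = NULL,
                          max_shift = 112L) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rot)) rot <- sample(c(0L, 90L, 180L, 270L), 1L)
  if (rot %% 90L != 0L) stop("rotation must be a multiple of 90", call. = FALSE)
  have_src <- !is.null(ortho) && !is.null(dsm)
  if (is.null(shift))
    shift <- if (have_src) sample(seq(-max_shift, max_shift), 2L, replace = TRUE)
             else c(0L, 0L)
  if (any(shift != 0L)) {
    if (!have_src)
      stop("translation requires the source rasters", call. = FALSE)
    window <- nrow(p$height)
    H <- nrow(dsm$data); W <- ncol(dsm$data)
    r0 <- min(max(p$origin[1] + shift[1], 0L), H - window)
    c0 <- min(max(p$origin[2] + shift[2], 0L), W - window)
    ri <- (r0 + 1L):(r0 + window); ci <- (c0 + 1L):(c0 + window)
    p <- list(rgb = ortho$data[ri, ci, , drop = FALSE],
              height = dsm$data[ri, ci],
              label = if (!is.null(labels)) labels$data[ri, ci] else p$label,
              origin = c(r0, c0))
  }
  k <- (rot %/% 90L) %% 4L
  p$rgb <- rot_k90(p$rgb, k)
  p$height <- rot_k90(p$height, k)
  if (!is.null(p$label)) p$label <- rot_k90(p$label, k)
  p
}

#' Assign patches to cross-validation folds
#'
#' Random partition into `n_folds` validation folds with sizes differing by
#' at most one; every patch lands in exactly one fold.
#'
#' @param patches list of patch records (only its length is used)
#' @param n_folds number of folds (default 5)
#' @param seed integer seed
#' @return list of class `fold_spec` with `n_folds`, `fold` (per-patch fold
#'   id), `seed`
#' @export
kfold_split <- function(patches, n_folds = 5L, seed = 1L) {
  n <- length(patches)
  n_folds <- as.integer(n_folds)
  if (n < n_folds) stop("split error: fewer patches than folds", call. = FALSE)
  set.seed(seed)
  fold <- integer(n)
  fold[sample.int(n)] <- rep(seq_len(n_folds), length.out = n)
  structure(list(n_folds = n_folds, fold = fold, seed = as.integer(seed)),
            class = "fold_spec")
}

#' Stitch overlapping patch predictions into a full-scene mask
#'
#' Class probabilities are averaged over all patches covering a cell, then
#' argmaxed (ties broken toward the lower class id). Cells covered by no
#' patch are nodata.
#'
#' @param preds list of `list(origin = c(row0, col0), probs = h x w x K)`
#'   with 0-based origins
#' @param extent `c(rows, cols)` of the output grid
#' @param template optional [reef_raster()] supplying the georeference
#' @return list with `label` (label [reef_raster()]) and `prob`
#'   (rows x cols x K array of averaged probabilities, `NA` where uncovered)
#' @export
stitch_predictions <- function(preds, extent, template = NULL) {
  if (length(preds) == 0L) stop("stitch error: empty prediction set", call. = FALSE)
  H <- extent[1]; W <- extent[2]
  K <- dim(preds[[1]]$probs)[3]
  sums <- array(0, c(H, W, K))
  count <- matrix(0L, H, W)
  for (p in preds) {
    h <- dim(p$probs)[1]; w <- dim(p$probs)[2]
    ri <- (p$origin[1] + 1L):(p$origin[1] + h)
    ci <- (p$origin[2] + 1L):(p$origin[2] + w)
    sums[ri, ci, ] <- sums[ri, ci, , drop = FALSE] + p$probs
    count[ri, ci] <- count[ri, ci] + 1L
  }
  covered <- count > 0L
  prob <- sums
  for (k in seq_len(K)) {
    pl <- prob[, , k]
    pl[covered] <- pl[covered] / count[covered]
    pl[!covered] <- NA
    prob[, , k] <- pl
  }
  pm <- matrix(prob, H * W, K)
  lab <- matrix(NA_real_, H, W)
  idx <- which(covered)
  lab[idx] <- max.col(pm[idx, , drop = FALSE], ties.method = "first") - 1
  geo <- if (!is.null(template)) c(template$x_origin, template$y_origin)
         else c(0, H * 0.001)
  cell <- if (!is.null(template)) template$cell else 0.001
  list(label = reef_raster(lab, geo, cell, "label"), prob = prob)
}
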
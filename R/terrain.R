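#' Slope and aspect by Horn's method
#'
#' Computes per-cell slope and aspect from a DSM with Horn's 3x3
#' finite-difference stencil (the ArcGIS default). Aspect is measured
#' clockwise from grid north; flat cells get aspect 0 (immaterial downstream
#' because `sin(slope) = 0` there). Border cells and cells with any nodata
#' neighbor are nodata.
#'
#' @param dsm a height [reef_raster()] with at least 3x3 cells
#' @return list with `slope` and `aspect` rasters (radians)
#' @export
slope_aspect <- function(dsm) {
  stopifnot(inherits(dsm, "reef_raster"))
  z <- dsm$data
  H <- nrow(z); W <- ncol(z)
  if (H < 3L || W < 3L) stop("terrain error: grid smaller than 3x3", call. = FALSE)
  sh <- function(dr, dc) z[(2 + dr):(H - 1 + dr), (2 + dc):(W - 1 + dc)]
  # compass neighbors of the interior cells
  nw <- sh(-1, -1); n <- sh(-1, 0); ne <- sh(-1, 1)
  wv <- sh(0, -1);                  ev <- sh(0, 1)
  sw <- sh(1, -1);  s <- sh(1, 0);  se <- sh(1, 1)
  p <- ((ne + 2 * ev + se) - (nw + 2 * wv + sw)) / (8 * dsm$cell)  # dz/dx east
  q <- ((nw + 2 * n + ne) - (sw + 2 * s + se)) / (8 * dsm$cell)    # dz/dy north
  slope <- atan(sqrt(p^2 + q^2))
  aspect <- atan2(-p, -q) %% (2 * pi)
  aspect[!is.na(slope) & slope == 0] <- 0
  full <- function(m) {
    out <- matrix(NA_real_, H, W)
    out[2:(H - 1), 2:(W - 1)] <- m
    out
  }
  geo <- c(dsm$x_origin, dsm$y_origin)
  list(slope = reef_raster(full(slope), geo, dsm$cell, "scalar"),
       aspect = reef_raster(full(aspect), geo, dsm$cell, "scalar"))
}

#' Unit surface normals from slope and aspect
#'
#' Decomposes the per-cell unit normal into components
#' `nx = sin(slope) sin(aspect)`, `ny = sin(slope) cos(aspect)`,
#' `nz = cos(slope)`.
#'
#' @param slope,aspect co-registered scalar rasters in radians
#' @return list of three co-registered rasters `nx`, `ny`, `nz`
#' @export
normals_from_slope_aspect <- function(slope, aspect) {
  assert_coregistered(slope, aspect)
  s <- slope$data; a <- aspect$data
  geo <- c(slope$x_origin, slope$y_origin)
  mk <- function(m) reef_raster(m, geo, slope$cell, "scalar")
  list(nx = mk(sin(s) * sin(a)), ny = mk(sin(s) * cos(a)), nz = mk(cos(s)))
}

# strict box sum: NA if any cell of the w x w window is NA or out of grid
box_sum_strict <- function(m, w) {
  h <- (w - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  valid <- !is.na(m)
  m0 <- m; m0[!valid] <- 0
  sat <- function(x) {
    s <- matrix(0, H + 1L, W + 1L)
    s[-1L, -1L] <- t(apply(apply(x, 2L, cumsum), 1L, cumsum))
    s
  }
  Sm <- sat(m0); Sv <- sat(valid + 0)
  rows <- (h + 1L):(H - h); cols <- (h + 1L):(W - h)
  win <- function(S) {
    S[rows + h + 1L, cols + h + 1L, drop = FALSE] -
      S[rows - h, cols + h + 1L, drop = FALSE] -
      S[rows + h + 1L, cols - h, drop = FALSE] +
      S[rows - h, cols - h, drop = FALSE]
  }
  sums <- win(Sm); counts <- win(Sv)
  sums[counts != w * w] <- NA
  out <- matrix(NA_real_, H, W)
  out[rows, cols] <- sums
  out
}

#' Vector Ruggedness Measure (VRM)
#'
#' Terrain rugosity in `[0, 1]`: per cell, the unit normals of the
#' `window_px x window_px` neighborhood are summed into a resultant vector
#' `R`; `vrm = 1 - |R| / n_cells`. 0 is a perfectly flat (or uniformly
#' tilted) surface, 1 maximal ruggedness. Windows containing any nodata cell
#' (including the normal-field border) yield nodata.
#'
#' @param dsm a height [reef_raster()]
#' @param window_px odd window size in cells, >= 3
#' @return list with `vrm` ([reef_raster()]) and `window_px`
#' @export
vrm <- function(dsm, window_px = 21L) {
  window_px <- as.integer(window_px)
  if (window_px < 3L || window_px %% 2L == 0L)
    stop("terrain error: window must be odd and >= 3", call. = FALSE)
  d <- dim(dsm$data)
  if (window_px > min(d[1], d[2]))
    stop("terrain error: window larger than grid", call. = FALSE)
  sa <- slope_aspect(dsm)
  nrm <- normals_from_slope_aspect(sa$slope, sa$aspect)
  sx <- box_sum_strict(nrm$nx$data, window_px)
  sy <- box_sum_strict(nrm$ny$data, window_px)
  sz <- box_sum_strict(nrm$nz$data, window_px)
  v <- 1 - sqrt(sx^2 + sy^2 + sz^2) / (window_px^2)
  out <- reef_raster(v, c(dsm$x_origin, dsm$y_origin), dsm$cell, "scalar")
  list(vrm = out, window_px = window_px)
}

#' DSM differencing (height change, mm)
#'
#' Pixel-wise subtraction of two co-registered DSMs, reported in millimeters
#' (`(t2 - t1) * 1000`). Nodata in either input propagates.
#'
#' @param dsm_t2,dsm_t1 height rasters for the later and earlier epoch
#' @return scalar [reef_raster()] of height change in mm
#' @export
dsm_difference <- function(dsm_t2, dsm_t1) {
  assert_coregistered(dsm_t2, dsm_t1)
  reef_raster((dsm_t2$data - dsm_t1$data) * 1000,
              c(dsm_t1$x_origin, dsm_t1$y_origin), dsm_t1$cell, "scalar")
}

summary_row <- function(v, class = NA, scale = NA) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (n == 0L)
    return(data.frame(class = class, scale = scale, n = 0L, min = NA_real_,
                      q1 = NA_real_, median = NA_real_, q3 = NA_real_,
                      max = NA_real_, mean = NA_real_, sd = NA_real_))
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(class = class, scale = scale, n = n, min = min(v), q1 = q[1],
             median = q[2], q3 = q[3], max = max(v), mean = mean(v),
             sd = stats::sd(v))
}

#' Summarise a height-change map
#'
#' Median, quartiles, mean, sd and a histogram of a change raster, optionally
#' restricted to the cells of one semantic class. The `[-50, 50]` mm display
#' truncation applies to the histogram range only, never to the statistics.
#'
#' @param change scalar [reef_raster()] in mm (from [dsm_difference()])
#' @param mask optional co-registered label raster
#' @param class_id optional class id selecting cells from `mask`
#' @param bin_width histogram bin width in mm (default 1)
#' @param hist_range histogram range in mm (default `c(-50, 50)`, values
#'   outside are clamped into the end bins)
#' @return list with `stats` (one-row data frame) and `histogram`
#'   (`mids`, `counts`)
#' @export
change_summary <- function(change, mask = NULL, class_id = NULL,
                           bin_width = 1, hist_range = c(-50, 50)) {
  v <- change$data
  if (!is.null(class_id)) {
    if (is.null(mask)) stop("stats error: class_id given without mask", call. = FALSE)
    assert_coregistered(change, mask)
    v[is.na(mask$data) | mask$data != class_id] <- NA
  }
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("stats error: empty selection", call. = FALSE)
  breaks <- seq(hist_range[1], hist_range[2], by = bin_width)
  vt <- pmin(pmax(v, hist_range[1]), hist_range[2])
  counts <- tabulate(findInterval(vt, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  list(stats = summary_row(v, class = if (is.null(class_id)) NA else class_id),
       histogram = list(mids = breaks[-length(breaks)] + bin_width / 2,
                        counts = counts))
}

#' Class-stratified summaries of a scalar field
#'
#' One summary row per class of `mask` (or per class id present on a labeled
#' cloud), for a scalar raster such as VRM or height change, or a per-point
#' scalar of a [labeled_cloud()]. Each cell/point is assigned its own class.
#'
#' @param values scalar [reef_raster()], or a [labeled_cloud()] with
#'   `scalar_name` naming a per-point scalar
#' @param mask co-registered label raster (ignored for clouds with labels)
#' @param scale optional scale annotation copied into the rows (e.g. window
#'   or radius)
#' @param scalar_name scalar to summarise when `values` is a cloud
#' @return data frame with columns class, scale, n, min, q1, median, q3, max,
#'   mean, sd (one row per class id 0..2; empty classes get `n = 0`)
#' @export
stratify_by_class <- function(values, mask = NULL, scale = NA,
                              scalar_name = NULL) {
  if (inherits(values, "labeled_cloud")) {
    if (is.null(scalar_name)) stop("scalar_name required for clouds", call. = FALSE)
    v <- values$scalars[[scalar_name]]
    if (is.null(v)) stop("unknown scalar: ", scalar_name, call. = FALSE)
    cls <- values$class_id
  } else {
    stopifnot(inherits(values, "reef_raster"))
    if (is.null(mask)) stop("mask required for rasters", call. = FALSE)
    assert_coregistered(values, mask)
    v <- as.vector(values$data)
    cls <- as.vector(mask$data)
  }
  keep <- !is.na(cls)
  v <- v[keep]; cls <- cls[keep]
  rows <- lapply(class_scheme()$ids, function(k) summary_row(v[cls == k], k, scale))
  do.call(rbind, rows)
}
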
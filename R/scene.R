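#' Parameters of a synthetic reef scene
#'
#' Describes a single-epoch synthetic fore-reef scene: a gently undulating
#' sand substrate with optional rock outcrops, plus non-overlapping
#' hemispherical coral colonies (live or dead) carrying fine branch-ridge
#' relief. Colors follow field display conventions: live coral dark pink,
#' dead coral pale pink (the intact white skeleton), sand tan, rock gray.
#' The dead-colony color is a parameter so that scenes can be made
#' RGB-confusable (dead coral colored like sand) to probe the value of the
#' height channel.
#'
#' @param extent_px `c(rows, cols)` grid size
#' @param cell cell size in m (default 0.001 = 1 mm)
#' @param n_colonies number of coral colonies
#' @param colony_radius_range radius range in m
#' @param colony_height_range apex height range in m
#' @param branch_ridge_amplitude amplitude of fine-scale ridge relief on
#'   colony surfaces, m
#' @param ridge_wavelength wavelength of the ridge texture, m
#' @param dead_fraction fraction of colonies initially dead
#' @param rock_fraction approximate fraction of scene area covered by rock
#'   outcrops (background class)
#' @param sand_noise_sd sd of per-cell height noise, m
#' @param illumination_gradient_amplitude amplitude of the multiplicative
#'   linear illumination gradient across the scene (unitless)
#' @param rgb_noise_sd sd of per-cell, per-channel RGB noise (0-255 units)
#' @param live_color,dead_color,sand_color,rock_color length-3 RGB in 0-255
#' @param seed integer seed; a fixed seed makes the scene bit-reproducible
#' @return list of class `scene_params`
#' @export
scene_params <- function(extent_px = c(512L, 512L), cell = 0.001,
                         n_colonies = 10L,
                         colony_radius_range = c(0.025, 0.05),
                         colony_height_range = c(0.03, 0.08),
                         branch_ridge_amplitude = 0.004,
                         ridge_wavelength = 0.012,
                         dead_fraction = 0.3,
                         rock_fraction = 0.05,
                         sand_noise_sd = 0.0005,
                         illumination_gradient_amplitude = 0.15,
                         rgb_noise_sd = 8,
                         live_color = c(199, 21, 133),
                         dead_color = c(244, 198, 207),
                         sand_color = c(210, 180, 140),
                         rock_color = c(120, 120, 120),
                         seed = 1L) {
  p <- list(extent_px = as.integer(extent_px), cell = cell,
            n_colonies = as.integer(n_colonies),
            colony_radius_range = colony_radius_range,
            colony_height_range = colony_height_range,
            branch_ridge_amplitude = branch_ridge_amplitude,
            ridge_wavelength = ridge_wavelength,
            dead_fraction = dead_fraction, rock_fraction = rock_fraction,
            sand_noise_sd = sand_noise_sd,
            illumination_gradient_amplitude = illumination_gradient_amplitude,
            rgb_noise_sd = rgb_noise_sd,
            live_color = live_color, dead_color = dead_color,
            sand_color = sand_color, rock_color = rock_color,
            seed = as.integer(seed))
  stopifnot(all(p$extent_px > 0), p$cell > 0,
            all(p$colony_radius_range > 0), all(p$colony_height_range > 0),
            p$dead_fraction >= 0, p$dead_fraction <= 1,
            p$rock_fraction >= 0, p$rock_fraction <= 1,
            p$sand_noise_sd >= 0, p$rgb_noise_sd >= 0)
  class(p) <- "scene_params"
  p
}

#' Prescribed change between two epochs of a synthetic scene
#'
#' @param growth_mm uniform vertical growth of surviving live colonies (mm)
#' @param mortality_fraction fraction of live colonies relabeled dead
#'   (skeleton intact: DSM unchanged)
#' @param removal_fraction fraction of coral colonies erased (height reverts
#'   to substrate, label to background)
#' @param seed integer seed for the mortality/removal draws
#' @param reilluminate redraw the illumination gradient for the new epoch
#'   (emulates changing light between surveys; off by default so background
#'   cells stay bit-identical)
#' @return list of class `epoch_delta`
#' @export
epoch_delta <- function(growth_mm = 0, mortality_fraction = 0,
                        removal_fraction = 0, seed = 1L,
                        reilluminate = FALSE) {
  if (!is.finite(growth_mm)) stop("parameter error: growth must be finite", call. = FALSE)
  if (mortality_fraction < 0 || mortality_fraction > 1 ||
      removal_fraction < 0 || removal_fraction > 1)
    stop("parameter error: fractions must be in [0, 1]", call. = FALSE)
  structure(list(growth_mm = growth_mm,
                 mortality_fraction = mortality_fraction,
                 removal_fraction = removal_fraction,
                 seed = as.integer(seed), reilluminate = reilluminate),
            class = "epoch_delta")
}

# smooth substrate: superposition of a few long-wavelength cosines
substrate_field <- function(H, W, cell) {
  xs <- ((1:W) - 0.5) * cell
  ys <- ((1:H) - 0.5) * cell
  ext <- max(H, W) * cell
  z <- matrix(0, H, W)
  for (k in 1:4) {
    th <- stats::runif(1, 0, 2 * pi)
    lam <- stats::runif(1, ext / 2, ext * 2)
    ph <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 0.002, 0.008)
    gx <- cos(th) * 2 * pi / lam
    gy <- sin(th) * 2 * pi / lam
    z <- z + amp * cos(outer(ys * gy, xs * gx, `+`) + ph)
  }
  z
}

# rejection-sample non-overlapping discs inside the extent (with a 4 mm gap
# so labeled footprints stay disconnected); larger discs first, which makes
# dense packings feasible
place_discs <- function(n, rmin, rmax, H, W, cell, existing, max_retries = 500L) {
  placed <- existing
  out <- NULL
  radii <- sort(stats::runif(n, rmin, rmax), decreasing = TRUE)
  for (i in seq_len(n)) {
    r <- radii[i]
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      x <- stats::runif(1, r + cell, W * cell - r - cell)
      y <- stats::runif(1, r + cell, H * cell - r - cell)
      if (x < 0 || y < 0) next
      clash <- FALSE
      if (!is.null(placed) && nrow(placed) > 0) {
        d <- sqrt((placed$x - x)^2 + (placed$y - y)^2)
        clash <- any(d < placed$radius + r + 0.004)
      }
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok)
      stop("generation error: could not place disc ", i,
           " without overlap after ", max_retries, " retries", call. = FALSE)
    row <- data.frame(x = x, y = y, radius = r)
    placed <- rbind(placed, row)
    out <- rbind(out, row)
  }
  out
}

# indices (vector over matrix cells) of cells within a disc, plus the radial
# fraction sqrt(1 - (d/r)^2) used as the bump profile
disc_footprint <- function(H, W, cell, cx, cy, r) {
  c0 <- max(1L, floor((cx - r) / cell)); c1 <- min(W, ceiling((cx + r) / cell) + 1L)
  r0 <- max(1L, floor((cy - r) / cell)); r1 <- min(H, ceiling((cy + r) / cell) + 1L)
  rows <- r0:r1; cols <- c0:c1
  xs <- (cols - 0.5) * cell
  ys <- (rows - 0.5) * cell
  dx2 <- outer(rep(1, length(rows)), (xs - cx)^2)
  dy2 <- outer((ys - cy)^2, rep(1, length(cols)))
  d2 <- dx2 + dy2
  inside <- d2 <= r^2
  idx <- which(inside)
  cellidx <- (rep(cols, each = length(rows))[idx] - 1L) * H + rep(rows, length(cols))[idx]
  profile <- sqrt(pmax(0, 1 - d2[idx] / r^2))
  list(idx = cellidx, profile = profile)
}

ridge_field <- function(H, W, cell, wavelength) {
  xs <- ((1:W) - 0.5) * cell
  ys <- ((1:H) - 0.5) * cell
  outer(sin(2 * pi * ys / wavelength), sin(2 * pi * xs / wavelength))
}

illumination_field <- function(H, W, amplitude) {
  th <- stats::runif(1, 0, 2 * pi)
  u <- outer(sin(th) * ((1:H) - (H + 1) / 2) / H,
             rep(1, W)) +
       outer(rep(1, H), cos(th) * ((1:W) - (W + 1) / 2) / W)
  1 + amplitude * 2 * u  # u in about [-1, 1]
}

render_ortho <- function(H, W, labels, rock_mask, p, illum) {
  base <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    m <- matrix(p$sand_color[ch], H, W)
    m[rock_mask] <- p$rock_color[ch]
    m[labels == 1] <- p$live_color[ch]
    m[labels == 2] <- p$dead_color[ch]
    base[, , ch] <- m
  }
  noise <- array(stats::rnorm(H * W * 3, 0, p$rgb_noise_sd), c(H, W, 3))
  out <- base * as.vector(illum) + noise
  out[out < 0] <- 0; out[out > 255] <- 255
  round(out)
}

#' Generate a synthetic reef scene
#'
#' Builds co-registered orthomosaic, DSM and label rasters plus a per-colony
#' truth table from [scene_params()]. The DSM is a smooth substrate plus
#' hemispherical colony bumps with fine ridge relief (kept on dead colonies:
#' the skeleton stays intact) and per-cell sand noise; the orthomosaic uses
#' class-dependent base colors under a linear illumination gradient with
#' additive noise.
#'
#' @param p a [scene_params()]
#' @return list of class `scene_bundle` with `ortho`, `dsm`, `labels`,
#'   `truth` (data frame: id, x, y, radius, class, height, type) and internal
#'   `fields` used by [evolve_scene()]
#' @export
generate_scene <- function(p) {
  stopifnot(inherits(p, "scene_params"))
  set.seed(p$seed)
  H <- p$extent_px[1]; W <- p$extent_px[2]
  substrate <- substrate_field(H, W, p$cell)
  # rocks first, then colonies, all mutually non-overlapping
  scene_area <- H * W * p$cell^2
  rocks <- NULL
  if (p$rock_fraction > 0) {
    rmin <- p$colony_radius_range[1] * 0.8
    rmax <- p$colony_radius_range[2]
    area <- 0
    while (area < p$rock_fraction * scene_area) {
      nxt <- tryCatch(place_discs(1L, rmin, rmax, H, W, p$cell, rocks),
                      error = function(e) NULL)
      if (is.null(nxt)) break
      rocks <- rbind(rocks, nxt)
      area <- area + pi * nxt$radius^2
    }
  }
  colonies <- if (p$n_colonies > 0)
    place_discs(p$n_colonies, p$colony_radius_range[1], p$colony_radius_range[2],
                H, W, p$cell, rocks)
  else NULL

  dsm <- substrate
  labels <- matrix(0, H, W)
  rock_mask <- matrix(FALSE, H, W)
  ridge <- ridge_field(H, W, p$cell, p$ridge_wavelength)
  truth <- NULL
  if (!is.null(rocks)) for (i in seq_len(nrow(rocks))) {
    fp <- disc_footprint(H, W, p$cell, rocks$x[i], rocks$y[i], rocks$radius[i])
    h <- stats::runif(1, 0.01, 0.025)
    dsm[fp$idx] <- dsm[fp$idx] + h * fp$profile
    rock_mask[fp$idx] <- TRUE
    truth <- rbind(truth, data.frame(x = rocks$x[i], y = rocks$y[i],
                                     radius = rocks$radius[i], class = 0L,
                                     height = h, type = "rock"))
  }
  if (!is.null(colonies)) {
    n <- nrow(colonies)
    n_dead <- floor(p$dead_fraction * n)
    dead_ids <- if (n_dead > 0) sample.int(n, n_dead) else integer(0)
    heights <- stats::runif(n, p$colony_height_range[1], p$colony_height_range[2])
    for (i in seq_len(n)) {
      fp <- disc_footprint(H, W, p$cell, colonies$x[i], colonies$y[i],
                           colonies$radius[i])
      cls <- if (i %in% dead_ids) 2L else 1L
      dsm[fp$idx] <- dsm[fp$idx] + heights[i] * fp$profile +
        p$branch_ridge_amplitude * ridge[fp$idx] * fp$profile
      labels[fp$idx] <- cls
      truth <- rbind(truth, data.frame(x = colonies$x[i], y = colonies$y[i],
                                       radius = colonies$radius[i], class = cls,
                                       height = heights[i], type = "coral"))
    }
  }
  if (p$sand_noise_sd > 0)
    dsm <- dsm + matrix(stats::rnorm(H * W, 0, p$sand_noise_sd), H, W)
  illum <- illumination_field(H, W, p$illumination_gradient_amplitude)
  ortho <- render_ortho(H, W, labels, rock_mask, p, illum)
  if (!is.null(truth)) truth <- cbind(id = seq_len(nrow(truth)), truth)
  origin <- c(0, H * p$cell)  # y_origin at the top edge
  structure(list(
    ortho = reef_raster(ortho, origin, p$cell, "rgb"),
    dsm = reef_raster(dsm, origin, p$cell, "height"),
    labels = reef_raster(labels, origin, p$cell, "label"),
    truth = truth,
    fields = list(substrate = substrate, illum = illum, rock_mask = rock_mask,
                  ridge = ridge, params = p)
  ), class = "scene_bundle")
}

#' @export
print.scene_bundle <- function(x, ...) {
  d <- dim(x$dsm$data)
  nc <- if (is.null(x$truth)) 0L else sum(x$truth$type == "coral")
  cat(sprintf("<scene_bundle: %d x %d cells (%.2f x %.2f m), %d coral colonies>\n",
              d[1], d[2], d[2] * x$dsm$cell, d[1] * x$dsm$cell, nc))
  invisible(x)
}

#' Evolve a synthetic scene to a second epoch
#'
#' Applies a prescribed [epoch_delta()]: surviving live colonies are raised
#' uniformly by `growth_mm`; a fraction of live colonies are relabeled dead
#' with the DSM unchanged (fresh mortality, skeleton intact); a fraction of
#' colonies are removed entirely (DSM reverts to the substrate, labels to
#' background). Cells outside affected colony footprints are bit-identical
#' to the input unless `reilluminate` is set.
#'
#' @param s a [generate_scene()] bundle
#' @param d an [epoch_delta()]
#' @return a new `scene_bundle`
#' @export
evolve_scene <- function(s, d) {
  stopifnot(inherits(s, "scene_bundle"), inherits(d, "epoch_delta"))
  p <- s$fields$params
  H <- nrow(s$dsm$data); W <- ncol(s$dsm$data)
  set.seed(d$seed)
  truth <- s$truth
  dsm <- s$dsm$data
  labels <- s$labels$data
  ortho <- s$ortho$data
  illum <- if (d$reilluminate)
    illumination_field(H, W, p$illumination_gradient_amplitude)
  else s$fields$illum
  if (d$reilluminate) {
    rmsk <- s$fields$rock_mask
    ortho <- render_ortho(H, W, labels, rmsk, p, illum)
  }
  coral <- which(!is.null(truth) & truth$type == "coral")
  removed <- integer(0); newly_dead <- integer(0)
  if (length(coral)) {
    n_rm <- floor(d$removal_fraction * length(coral))
    if (n_rm > 0) removed <- sort(sample(coral, n_rm))
    live <- setdiff(coral[truth$class[coral] == 1L], removed)
    n_mort <- floor(d$mortality_fraction * length(live))
    if (n_mort > 0) newly_dead <- sort(sample(live, n_mort))
  }
  recolor <- function(idx, color) {
    nse <- matrix(stats::rnorm(length(idx) * 3, 0, p$rgb_noise_sd), ncol = 3)
    for (ch in 1:3) {
      plane <- ortho[, , ch]
      v <- color[ch] * illum[idx] + nse[, ch]
      plane[idx] <- round(pmin(pmax(v, 0), 255))
      ortho[, , ch] <<- plane
    }
  }
  for (i in removed) {
    fp <- disc_footprint(H, W, p$cell, truth$x[i], truth$y[i], truth$radius[i])
    dsm[fp$idx] <- s$fields$substrate[fp$idx] +
      stats::rnorm(length(fp$idx), 0, p$sand_noise_sd)
    labels[fp$idx] <- 0L
    recolor(fp$idx, p$sand_color)
    truth$class[i] <- 0L
  }
  for (i in newly_dead) {
    fp <- disc_footprint(H, W, p$cell, truth$x[i], truth$y[i], truth$radius[i])
    labels[fp$idx] <- 2L
    recolor(fp$idx, p$dead_color)
    truth$class[i] <- 2L
  }
  surviving_live <- setdiff(coral[s$truth$class[coral] == 1L],
                            c(removed, newly_dead))
  g <- d$growth_mm / 1000
  if (g != 0) for (i in surviving_live) {
    fp <- disc_footprint(H, W, p$cell, truth$x[i], truth$y[i], truth$radius[i])
    dsm[fp$idx] <- dsm[fp$idx] + g
    truth$height[i] <- truth$height[i] + g
  }
  truth$removed <- seq_len(nrow(truth)) %in% removed
  origin <- c(s$dsm$x_origin, s$dsm$y_origin)
  structure(list(
    ortho = reef_raster(ortho, origin, p$cell, "rgb"),
    dsm = reef_raster(dsm, origin, p$cell, "height"),
    labels = reef_raster(labels, origin, p$cell, "label"),
    truth = truth,
    fields = list(substrate = s$fields$substrate, illum = illum,
                  rock_mask = s$fields$rock_mask, ridge = s$fields$ridge,
                  params = p)
  ), class = "scene_bundle")
}

# bilinear interpolation of a DSM at world coordinates; falls back to the
# containing cell's value where a corner is nodata or outside the grid
dsm_bilinear <- function(dsm, x, y) {
  z <- dsm$data
  H <- nrow(z); W <- ncol(z)
  gc <- (x - dsm$x_origin) / dsm$cell - 0.5   # 0-based fractional col at centers
  gr <- (dsm$y_origin - y) / dsm$cell - 0.5
  gc <- pmin(pmax(gc, 0), W - 1); gr <- pmin(pmax(gr, 0), H - 1)
  c0 <- pmin(floor(gc), W - 2); r0 <- pmin(floor(gr), H - 2)
  fc <- gc - c0; fr <- gr - r0
  i00 <- r0 + 1 + c0 * H
  z00 <- z[i00]; z01 <- z[i00 + H]; z10 <- z[i00 + 1]; z11 <- z[i00 + H + 1]
  out <- z00 * (1 - fr) * (1 - fc) + z01 * (1 - fr) * fc +
         z10 * fr * (1 - fc) + z11 * fr * fc
  bad <- is.na(out)
  if (any(bad)) {
    rc <- raster_xy_to_rowcol(dsm, x[bad], y[bad])
    rr <- pmin(pmax(rc[, 1], 1L), H); cc <- pmin(pmax(rc[, 2], 1L), W)
    out[bad] <- z[cbind(rr, cc)]
  }
  out
}

#' Sample a labeled point cloud from a scene
#'
#' Draws `points_per_cell` points per valid DSM cell, with optional uniform
#' (x, y) jitter inside the cell; `z` is the bilinear DSM surface at the
#' jittered position and each point carries the class of its source cell.
#'
#' @param s a `scene_bundle`
#' @param points_per_cell integer density (default 1)
#' @param jitter logical; with `FALSE`, points sit exactly on cell centers
#' @param seed optional seed for the jitter
#' @return a [labeled_cloud()]
#' @export
sample_point_cloud <- function(s, points_per_cell = 1L, jitter = TRUE,
                               seed = NULL) {
  stopifnot(inherits(s, "scene_bundle"), points_per_cell > 0)
  if (!is.null(seed)) set.seed(seed)
  z <- s$dsm$data
  H <- nrow(z); W <- ncol(z)
  valid <- which(!is.na(z))
  rows <- ((valid - 1L) %% H) + 1L
  cols <- ((valid - 1L) %/% H) + 1L
  d <- as.integer(points_per_cell)
  rows <- rep(rows, d); cols <- rep(cols, d)
  n <- length(rows)
  ctr <- raster_rowcol_to_xy(s$dsm, rows, cols)
  if (jitter) {
    x <- ctr[, 1] + stats::runif(n, -0.5, 0.5) * s$dsm$cell
    y <- ctr[, 2] + stats::runif(n, -0.5, 0.5) * s$dsm$cell
  } else {
    x <- ctr[, 1]; y <- ctr[, 2]
  }
  zz <- dsm_bilinear(s$dsm, x, y)
  cls <- as.integer(s$labels$data[cbind(rows, cols)])
  labeled_cloud(cbind(x, y, zz), class_id = cls)
}

#' Triangulate a scene DSM into a height-field mesh
#'
#' One vertex per valid DSM cell at its cell-center world coordinate and
#' height, two counter-clockwise (upward-facing) triangles per complete
#' 2x2 quad of valid cells. Vertex order is deterministic (column-major over
#' the grid). If the scene carries labels, vertices get a `class_id`
#' attribute.
#'
#' @param s a `scene_bundle` or a height [reef_raster()]
#' @return a [tri_mesh()]
#' @export
build_mesh <- function(s) {
  dsm <- if (inherits(s, "scene_bundle")) s$dsm else s
  stopifnot(inherits(dsm, "reef_raster"), dsm$meaning %in% c("height", "scalar"))
  z <- dsm$data
  H <- nrow(z); W <- ncol(z)
  if (H < 2L || W < 2L) stop("mesh error: need at least 2x2 cells", call. = FALSE)
  valid <- !is.na(z)
  vidx <- matrix(NA_integer_, H, W)
  vcells <- which(valid)
  vidx[vcells] <- seq_along(vcells)
  rows <- ((vcells - 1L) %% H) + 1L
  cols <- ((vcells - 1L) %/% H) + 1L
  xy <- raster_rowcol_to_xy(dsm, rows, cols)
  verts <- cbind(xy[, 1], xy[, 2], z[vcells])
  # quads whose 4 corners are valid
  q <- which(valid[-H, -W] & valid[-1, -W] & valid[-H, -1] & valid[-1, -1])
  if (length(q) == 0L) stop("mesh error: no complete 2x2 quad of valid cells",
                            call. = FALSE)
  qr <- ((q - 1L) %% (H - 1L)) + 1L
  qc <- ((q - 1L) %/% (H - 1L)) + 1L
  v00 <- vidx[cbind(qr, qc)];     v01 <- vidx[cbind(qr, qc + 1L)]
  v10 <- vidx[cbind(qr + 1L, qc)]; v11 <- vidx[cbind(qr + 1L, qc + 1L)]
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  attrs <- list()
  if (inherits(s, "scene_bundle"))
    attrs$class_id <- as.numeric(s$labels$data[vcells])
  tri_mesh(verts, faces, attrs)
}

#' Write a scene bundle to disk
#'
#' Writes the orthomosaic (`ortho.tif` + world file), DSM (`dsm.asc`),
#' labels (`labels.asc`), truth table (`truth.csv`), a sampled point cloud
#' (`cloud.ply`) and height-field mesh (`mesh.ply`).
#'
#' @param s a `scene_bundle`
#' @param dir output directory (created if needed)
#' @param cloud_density points per cell for the exported cloud (0 skips it)
#' @return invisibly the vector of written paths
#' @export
write_scene <- function(s, dir, cloud_density = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    save_raster(s$ortho, file.path(dir, "ortho.tif")),
    save_raster(s$dsm, file.path(dir, "dsm.asc")),
    save_raster(s$labels, file.path(dir, "labels.asc"))
  )
  if (!is.null(s$truth)) {
    tp <- file.path(dir, "truth.csv")
    utils::write.csv(s$truth, tp, row.names = FALSE)
    paths <- c(paths, tp)
  }
  if (cloud_density > 0) {
    cl <- sample_point_cloud(s, cloud_density, jitter = FALSE)
    cp <- file.path(dir, "cloud.ply")
    write_ply(cl, cp)
    mp <- file.path(dir, "mesh.ply")
    write_ply(build_mesh(s), mp)
    paths <- c(paths, cp, mp)
  }
  invisible(paths)
}
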
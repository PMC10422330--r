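#' Labeled point cloud
#'
#' An N x 3 matrix of metric coordinates with an optional per-point class id
#' and named per-point scalars (e.g. `roughness_r20`).
#'
#' @param xyz N x 3 numeric matrix (m); must be finite
#' @param class_id optional integer vector of per-point class ids (`NA` =
#'   unset)
#' @param scalars named list of per-point numeric vectors
#' @return object of class `labeled_cloud`
#' @export
labeled_cloud <- function(xyz, class_id = NULL, scalars = list()) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns", call. = FALSE)
  if (nrow(xyz) && any(!is.finite(xyz)))
    stop("cloud coordinates must be finite", call. = FALSE)
  colnames(xyz) <- c("x", "y", "z")
  if (!is.null(class_id)) {
    class_id <- as.integer(class_id)
    if (length(class_id) != nrow(xyz))
      stop("class_id length mismatch", call. = FALSE)
  }
  for (s in scalars) if (length(s) != nrow(xyz))
    stop("scalar length mismatch", call. = FALSE)
  structure(list(xyz = xyz, class_id = class_id, scalars = scalars),
            class = "labeled_cloud")
}

#' @export
print.labeled_cloud <- function(x, ...) {
  cat(sprintf("<labeled_cloud: %d points%s%s>\n", nrow(x$xyz),
              if (!is.null(x$class_id)) ", labeled" else "",
              if (length(x$scalars))
                paste0(", scalars: ", paste(names(x$scalars), collapse = ", "))
              else ""))
  invisible(x)
}

#' Indices of points within a radius of a query point
#'
#' Euclidean ball neighborhood, excluding the query point itself.
#'
#' @param cloud a [labeled_cloud()]
#' @param i query point index
#' @param radius radius in m
#' @return integer vector of neighbor indices
#' @export
radius_neighbors <- function(cloud, i, radius) {
  stopifnot(radius > 0)
  p <- cloud$xyz[i, ]
  d2 <- (cloud$xyz[, 1] - p[1])^2 + (cloud$xyz[, 2] - p[2])^2 +
        (cloud$xyz[, 3] - p[3])^2
  out <- which(d2 <= radius^2)
  out[out != i]
}

#' Total-least-squares plane fit
#'
#' Fits a plane through >= 3 non-collinear points: centroid plus the
#' eigenvector of the smallest eigenvalue of the point covariance.
#'
#' @param points n x 3 matrix
#' @return list of class `plane_fit` with `centroid`, `normal` (unit),
#'   `rms` residual; degenerate inputs raise a condition of class
#'   `reef3d_degenerate_fit`.
#' @export
fit_plane <- function(points) {
  points <- as.matrix(points)
  degenerate <- function(msg)
    stop(errorCondition(msg, class = c("reef3d_degenerate_fit", "error")))
  if (nrow(points) < 3L) degenerate("plane fit needs >= 3 points")
  cen <- colMeans(points)
  d <- sweep(points, 2L, cen)
  cov <- crossprod(d) / nrow(points)
  e <- eigen(cov, symmetric = TRUE)
  # eigenvalues descending; collinear sets have two ~zero eigenvalues
  if (e$values[1] <= 0 || e$values[2] <= 1e-12 * e$values[1])
    degenerate("collinear or coincident points")
  nrm <- e$vectors[, 3L]
  res <- as.vector(d %*% nrm)
  structure(list(centroid = cen, normal = nrm, rms = sqrt(mean(res^2))),
            class = "plane_fit")
}

#' Multi-scale point-cloud roughness
#'
#' For each point and each radius, the perpendicular distance of the point to
#' the total-least-squares plane of its neighbors within that radius (the
#' point itself excluded). Points with fewer than 3 neighbors, or a
#' degenerate (collinear) neighborhood, get `NA`. Results are stored as
#' per-point scalars named `roughness_r<mm>`.
#'
#' @param cloud a [labeled_cloud()]
#' @param radii numeric vector of radii in m (e.g. `c(0.02, 0.05, 0.1)`)
#' @return the cloud with one added scalar per radius
#' @export
roughness <- function(cloud, radii = c(0.02, 0.05, 0.1)) {
  stopifnot(inherits(cloud, "labeled_cloud"), all(radii > 0))
  for (r in radii) {
    nm <- sprintf("roughness_r%g", r * 1000)
    cloud$scalars[[nm]] <- as.numeric(roughness_cpp(cloud$xyz, r))
  }
  cloud
}

#' Transfer raster labels to a point cloud
#'
#' Each point receives the class of the raster cell containing its (x, y);
#' points outside the raster extent or over nodata cells stay unset (`NA`).
#'
#' @param cloud a [labeled_cloud()]
#' @param mask a label [reef_raster()] in the same coordinate frame
#' @return the cloud with `class_id` set
#' @export
transfer_labels <- function(cloud, mask) {
  stopifnot(inherits(cloud, "labeled_cloud"), inherits(mask, "reef_raster"))
  rc <- raster_xy_to_rowcol(mask, cloud$xyz[, 1], cloud$xyz[, 2])
  H <- nrow(mask$data); W <- ncol(mask$data)
  cls <- rep(NA_integer_, nrow(cloud$xyz))
  ok <- rc[, 1] >= 1L & rc[, 1] <= H & rc[, 2] >= 1L & rc[, 2] <= W
  cls[ok] <- as.integer(mask$data[rc[ok, , drop = FALSE]])
  cloud$class_id <- cls
  cloud
}

## ---- ASCII PLY I/O ----

ply_na <- function(v) { v[is.na(v)] <- NaN; v }

#' Write a point cloud or mesh as ASCII PLY
#'
#' Vertex coordinates are written as doubles; `class_id` as int (`NA` as -1),
#' colors as uchar `red`/`green`/`blue`, other per-vertex scalars as doubles
#' (`NA` as `nan`). Meshes also get a face element.
#'
#' @param x a [labeled_cloud()] or [tri_mesh()]
#' @param path destination `.ply` path
#' @return invisibly `path`
#' @export
write_ply <- function(x, path) {
  if (inherits(x, "labeled_cloud")) {
    verts <- x$xyz; faces <- NULL
    attrs <- x$scalars
    if (!is.null(x$class_id)) attrs <- c(list(class_id = x$class_id), attrs)
  } else if (inherits(x, "tri_mesh")) {
    verts <- x$vertices; faces <- x$faces; attrs <- x$vertex_attrs
  } else stop("write_ply: unsupported object", call. = FALSE)
  n <- nrow(verts)
  cols <- list(verts[, 1], verts[, 2], verts[, 3])
  props <- c("property double x", "property double y", "property double z")
  fmt <- c("%.17g", "%.17g", "%.17g")
  color <- attrs[["color"]]
  attrs[["color"]] <- NULL
  if (!is.null(color)) {
    for (k in 1:3) cols[[length(cols) + 1L]] <- as.integer(round(color[, k]))
    props <- c(props, paste("property uchar", c("red", "green", "blue")))
    fmt <- c(fmt, rep("%d", 3))
  }
  for (nm in names(attrs)) {
    v <- attrs[[nm]]
    if (nm == "class_id") {
      vi <- as.integer(v); vi[is.na(vi)] <- -1L
      cols[[length(cols) + 1L]] <- vi
      props <- c(props, "property int class_id")
      fmt <- c(fmt, "%d")
    } else {
      cols[[length(cols) + 1L]] <- ply_na(as.numeric(v))
      props <- c(props, paste("property double", nm))
      fmt <- c(fmt, "%.17g")
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", n), props,
               if (!is.null(faces))
                 c(sprintf("element face %d", nrow(faces)),
                   "property list uchar int vertex_indices"),
               "end_header"), con)
  writeLines(do.call(sprintf, c(list(paste(fmt, collapse = " ")), cols)), con)
  if (!is.null(faces))
    writeLines(sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L,
                       faces[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY file
#'
#' Returns a [tri_mesh()] when the file has faces, otherwise a
#' [labeled_cloud()]. `class_id` values of -1 and `nan` scalars become `NA`.
#'
#' @param path a `.ply` path
#' @return [tri_mesh()] or [labeled_cloud()]
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("^format ascii", lines[2]))
    stop("format error: only ASCII PLY is supported", call. = FALSE)
  hend <- match("end_header", lines)
  header <- lines[seq_len(hend)]
  nv <- 0L; nf <- 0L; vprops <- character(0); in_vertex <- FALSE
  for (l in header) {
    t <- strsplit(trimws(l), "\\s+")[[1]]
    if (t[1] == "element") {
      in_vertex <- t[2] == "vertex"
      if (t[2] == "vertex") nv <- as.integer(t[3])
      if (t[2] == "face") nf <- as.integer(t[3])
    } else if (t[1] == "property" && in_vertex && t[2] != "list") {
      vprops <- c(vprops, t[3])
    }
  }
  body <- lines[(hend + 1L):length(lines)]
  vdat <- matrix(scan(text = body[seq_len(nv)], what = double(), quiet = TRUE),
                 nrow = nv, byrow = TRUE)
  colnames(vdat) <- vprops
  xyz <- vdat[, c("x", "y", "z"), drop = FALSE]
  attrs <- list()
  for (nm in setdiff(vprops, c("x", "y", "z"))) {
    v <- vdat[, nm]
    if (nm == "class_id") {
      v <- as.integer(v)
      v[v < 0] <- NA_integer_
    } else {
      v[is.nan(v)] <- NA
    }
    attrs[[nm]] <- v
  }
  color <- NULL
  if (all(c("red", "green", "blue") %in% names(attrs))) {
    color <- cbind(attrs$red, attrs$green, attrs$blue)
    attrs$red <- attrs$green <- attrs$blue <- NULL
  }
  if (nf > 0L) {
    fdat <- matrix(scan(text = body[nv + seq_len(nf)], what = double(),
                        quiet = TRUE), nrow = nf, byrow = TRUE)
    faces <- fdat[, 2:4, drop = FALSE] + 1L
    storage.mode(faces) <- "integer"
    if (!is.null(color)) attrs$color <- color
    tri_mesh(xyz, faces, attrs)
  } else {
    cls <- attrs$class_id
    attrs$class_id <- NULL
    if (!is.null(color)) attrs$color <- NULL
    labeled_cloud(xyz, class_id = cls, scalars = attrs)
  }
}
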
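#' Triangle mesh with per-vertex attributes
#'
#' @param vertices V x 3 numeric matrix (m)
#' @param faces F x 3 integer matrix of 1-based vertex indices
#' @param vertex_attrs named list of per-vertex attributes; `color` is a
#'   V x 3 RGB matrix in 0-255, others are numeric vectors
#' @return object of class `tri_mesh`
#' @export
tri_mesh <- function(vertices, faces, vertex_attrs = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be V x 3", call. = FALSE)
  if (ncol(faces) != 3L) stop("faces must be F x 3", call. = FALSE)
  if (nrow(faces)) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face index out of range", call. = FALSE)
    if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
            faces[, 2] == faces[, 3]))
      stop("degenerate face (repeated vertex index)", call. = FALSE)
  }
  for (nm in names(vertex_attrs)) {
    a <- vertex_attrs[[nm]]
    len <- if (is.matrix(a)) nrow(a) else length(a)
    if (len != nrow(vertices))
      stop("vertex attribute length mismatch: ", nm, call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces,
                 vertex_attrs = vertex_attrs),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh: %d vertices, %d faces%s>\n",
              nrow(x$vertices), nrow(x$faces),
              if (length(x$vertex_attrs))
                paste0(", attrs: ", paste(names(x$vertex_attrs), collapse = ", "))
              else ""))
  invisible(x)
}

#' Unit face normals of a triangle mesh
#'
#' @param mesh a [tri_mesh()]
#' @return F x 3 matrix of unit normals (right-hand rule over vertex order)
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n / sqrt(rowSums(n^2))
}

#' Project a raster onto mesh vertices
#'
#' Each vertex receives the raster value at its (x, y): nearest-cell lookup
#' for label rasters (categorical data is never interpolated), bilinear
#' interpolation for scalar/height rasters. Vertices outside the raster or
#' over nodata stay `NA`. Re-projecting the same raster is idempotent; an
#' existing attribute of the same name is overwritten with a warning.
#'
#' @param mesh a [tri_mesh()]
#' @param r a [reef_raster()] in the same coordinate frame
#' @param attr_name name of the vertex attribute to create
#' @return the mesh with the attribute added
#' @export
project_raster_to_mesh <- function(mesh, r, attr_name) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(r, "reef_raster"))
  if (attr_name %in% names(mesh$vertex_attrs))
    warning("overwriting existing vertex attribute: ", attr_name)
  x <- mesh$vertices[, 1]; y <- mesh$vertices[, 2]
  H <- nrow(r$data); W <- ncol(r$data)
  rc <- raster_xy_to_rowcol(r, x, y)
  inside <- rc[, 1] >= 1L & rc[, 1] <= H & rc[, 2] >= 1L & rc[, 2] <= W
  vals <- rep(NA_real_, nrow(mesh$vertices))
  if (r$meaning == "label") {
    vals[inside] <- r$data[rc[inside, , drop = FALSE]]
  } else {
    vals[inside] <- dsm_bilinear(r, x[inside], y[inside])
    # nodata at the containing cell voids the vertex
    nd <- inside
    nd[inside] <- is.na(r$data[rc[inside, , drop = FALSE]])
    vals[nd] <- NA_real_
  }
  mesh$vertex_attrs[[attr_name]] <- vals
  mesh
}

#' Colorize mesh vertices from an attribute
#'
#' Class attributes use the benthic display colors (live dark pink, dead
#' light pink, background gray). Scalar change attributes use a diverging
#' red-white-blue map over `[-50, 50]` mm: red is an increase, blue a
#' decrease, white no change; values beyond the range are clamped (the
#' standard +-50 mm display truncation).
#'
#' @param mesh a [tri_mesh()]
#' @param attr_name vertex attribute to map
#' @param scheme `"class"` or `"diverging"`
#' @param range clamp range for the diverging map (mm)
#' @return mesh with a `color` vertex attribute (V x 3, 0-255); `NA`
#'   attribute values render mid-gray
#' @export
colorize <- function(mesh, attr_name, scheme = c("class", "diverging"),
                     range = c(-50, 50)) {
  scheme <- match.arg(scheme)
  v <- mesh$vertex_attrs[[attr_name]]
  if (is.null(v)) stop("unknown attribute: ", attr_name, call. = FALSE)
  n <- length(v)
  col <- matrix(128, n, 3)
  if (scheme == "class") {
    cs <- class_scheme()
    pal <- t(grDevices::col2rgb(cs$colors))
    for (k in seq_along(cs$ids)) {
      sel <- !is.na(v) & v == cs$ids[k]
      if (any(sel)) col[sel, ] <- matrix(pal[k, ], sum(sel), 3, byrow = TRUE)
    }
  } else {
    t0 <- pmin(pmax(v, range[1]), range[2]) / max(abs(range))
    ok <- !is.na(t0)
    tp <- pmax(t0[ok], 0); tn <- pmax(-t0[ok], 0)
    col[ok, 1] <- 255 * (1 - tn)
    col[ok, 2] <- 255 * (1 - pmax(tp, tn))
    col[ok, 3] <- 255 * (1 - tp)
  }
  mesh$vertex_attrs$color <- round(col)
  mesh
}

#' Write a mesh as Wavefront OBJ
#'
#' Vertices and faces only: OBJ has no standard per-vertex color or scalar
#' channel, so attributes are dropped (use PLY to keep them).
#'
#' @param mesh a [tri_mesh()]
#' @param path destination `.obj` path
#' @return invisibly `path`
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}
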
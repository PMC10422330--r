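#' Georeferenced raster container
#'
#' A `reef_raster` holds a single- or three-band axis-aligned, north-up grid
#' together with its affine georeference (origin of the top-left corner, square
#' cell size) and the nodata sentinel used on disk. Internally nodata cells are
#' stored as `NA`; the sentinel is only applied when writing. Pixel
#' `(row, col)` (1-based) maps to the world coordinate of its cell center:
#' `x = x_origin + (col - 0.5) * cell`, `y = y_origin - (row - 0.5) * cell`.
#'
#' @param data numeric matrix (`rows x cols`) for single-band rasters or a
#'   `rows x cols x 3` array for RGB. `NA` marks nodata.
#' @param origin numeric length-2, `c(x_origin, y_origin)` of the top-left
#'   *corner* of the grid, in meters.
#' @param cell cell size in meters (default 0.001, i.e. 1 mm).
#' @param meaning band meaning, one of `"rgb"`, `"height"`, `"label"`,
#'   `"scalar"`.
#' @param nodata sentinel value used on disk; defaults to 255 for labels and
#'   -9999 otherwise.
#' @return an object of class `reef_raster`.
#' @export
reef_raster <- function(data, origin = c(0, 0), cell = 0.001,
                        meaning = c("scalar", "rgb", "height", "label"),
                        nodata = NULL) {
  meaning <- match.arg(meaning)
  if (meaning == "rgb") {
    if (!(is.array(data) && length(dim(data)) == 3L && dim(data)[3] == 3L))
      stop("rgb raster requires a rows x cols x 3 array", call. = FALSE)
  } else {
    if (!is.matrix(data))
      stop(sprintf("%s raster requires a matrix", meaning), call. = FALSE)
  }
  if (!is.numeric(data)) stop("raster data must be numeric", call. = FALSE)
  storage.mode(data) <- "double"

  if (length(origin) != 2L || !is.numeric(origin) || any(!is.finite(origin)))
    stop("origin must be finite numeric length 2", call. = FALSE)
  if (!is.numeric(cell) || length(cell) != 1L || cell <= 0)
    stop("cell size must be a positive scalar", call. = FALSE)
  if (is.null(nodata)) nodata <- if (meaning == "label") 255 else -9999
  if (meaning == "label") {
    v <- data[!is.na(data)]
    if (length(v) && !all(v %in% c(0, 1, 2)))
      stop("label raster contains values outside {0, 1, 2}", call. = FALSE)
  }
  if (meaning == "height") {
    v <- data[!is.na(data)]
    if (length(v) && any(!is.finite(v)))
      stop("height raster contains non-finite values", call. = FALSE)
  }
  structure(
    list(data = data, x_origin = origin[1], y_origin = origin[2],
         cell = cell, nodata = nodata, meaning = meaning),
    class = "reef_raster"
  )
}

#' @export
print.reef_raster <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<reef_raster: %s, %d x %d%s, cell %g m, origin (%g, %g)>\n",
              x$meaning, d[1], d[2],
              if (length(d) == 3L) sprintf(" x %d", d[3]) else "",
              x$cell, x$x_origin, x$y_origin))
  nv <- sum(!is.na(if (x$meaning == "rgb") x$data[, , 1] else x$data))
  cat(sprintf("  valid cells: %d / %d; nodata sentinel %g\n",
              nv, d[1] * d[2], x$nodata))
  invisible(x)
}

#' @export
dim.reef_raster <- function(x) dim(x$data)

#' Benthic class scheme
#'
#' Class ids, names and display colors for the three benthic classes:
#' background (0), live coral (1), dead coral (2). Live coral renders dark
#' pink, dead coral light pink, background dark gray.
#'
#' @return list with `ids`, `names`, `colors` (hex, named by class name).
#' @export
class_scheme <- function() {
  list(ids = 0:2,
       names = c("background", "live", "dead"),
       colors = c(background = "#3C3C3C", live = "#C71585", dead = "#F4C6CF"))
}

raster_ncells <- function(r) prod(dim(r$data)[1:2])

#' Convert raster row/col indices to world coordinates of cell centers
#' @param r a `reef_raster`
#' @param row,col 1-based indices (vectors of equal length)
#' @return matrix with columns `x`, `y` (m)
#' @export
raster_rowcol_to_xy <- function(r, row, col) {
  cbind(x = r$x_origin + (col - 0.5) * r$cell,
        y = r$y_origin - (row - 0.5) * r$cell)
}

#' Convert world coordinates to the raster cell containing them
#' @param r a `reef_raster`
#' @param x,y world coordinates (m)
#' @return integer matrix with columns `row`, `col`; indices may fall outside
#'   `dim(r)` for points beyond the extent.
#' @export
raster_xy_to_rowcol <- function(r, x, y) {
  cbind(row = as.integer(floor((r$y_origin - y) / r$cell) + 1),
        col = as.integer(floor((x - r$x_origin) / r$cell) + 1))
}

#' Check that two rasters share grid and georeference exactly
#'
#' All downstream stages that combine two rasters call this first; shapes,
#' origins and cell sizes must match exactly.
#'
#' @param a,b `reef_raster` objects
#' @return invisibly `TRUE`; otherwise an error naming the differing field.
#' @export
assert_coregistered <- function(a, b) {
  da <- dim(a$data)[1:2]; db <- dim(b$data)[1:2]
  if (!identical(da, db))
    stop(sprintf("co-registration error: shapes differ (%dx%d vs %dx%d)",
                 da[1], da[2], db[1], db[2]), call. = FALSE)
  if (a$cell != b$cell)
    stop(sprintf("co-registration error: cell sizes differ (%g vs %g)",
                 a$cell, b$cell), call. = FALSE)
  if (a$x_origin != b$x_origin || a$y_origin != b$y_origin)
    stop(sprintf("co-registration error: origins differ ((%g,%g) vs (%g,%g))",
                 a$x_origin, a$y_origin, b$x_origin, b$y_origin), call. = FALSE)
  invisible(TRUE)
}

default_nodata <- function(meaning) if (meaning == "label") 255 else -9999

## ---- ESRI ASCII grid (single band) ----

read_ascii_grid <- function(path) {
  head <- readLines(path, n = 6L)
  kv <- lapply(strsplit(trimws(head), "\\s+"), function(p)
    c(toupper(p[1]), p[2]))
  keys <- vapply(kv, `[`, "", 1L)
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER", "CELLSIZE")
  if (!all(need %in% keys))
    stop("format error: not an ESRI ASCII grid: ", path, call. = FALSE)
  nc <- as.integer(vals[["NCOLS"]]); nr <- as.integer(vals[["NROWS"]])
  nd <- if ("NODATA_VALUE" %in% keys) vals[["NODATA_VALUE"]] else NA_real_
  nskip <- if ("NODATA_VALUE" %in% keys) 6L else 5L
  v <- scan(path, what = double(), skip = nskip, quiet = TRUE)
  if (length(v) != nr * nc)
    stop("format error: cell count mismatch in ", path, call. = FALSE)
  m <- matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.na(nd)) m[m == nd] <- NA
  list(data = m,
       origin = c(vals[["XLLCORNER"]], vals[["YLLCORNER"]] + nr * vals[["CELLSIZE"]]),
       cell = vals[["CELLSIZE"]],
       nodata = if (is.na(nd)) NULL else nd)
}

write_ascii_grid <- function(r, path) {
  m <- r$data
  nr <- nrow(m); nc <- ncol(m)
  m[is.na(m)] <- r$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("NCOLS %d", nc),
    sprintf("NROWS %d", nr),
    sprintf("XLLCORNER %.17g", r$x_origin),
    sprintf("YLLCORNER %.17g", r$y_origin - nr * r$cell),
    sprintf("CELLSIZE %.17g", r$cell),
    sprintf("NODATA_VALUE %.17g", r$nodata)
  ), con)
  writeLines(apply(m, 1L, function(row) paste(sprintf("%.17g", row), collapse = " ")),
             con)
}

## ---- world file + JSON sidecar for TIFF/PNG ----

world_file_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  sub(sprintf("\\.%s$", ext), switch(ext, tif = ".tfw", tiff = ".tfw", png = ".pgw",
                                     ".wld"), path, ignore.case = TRUE)
}

write_world_file <- function(r, path) {
  writeLines(sprintf("%.17g", c(r$cell, 0, 0, -r$cell,
                                r$x_origin + r$cell / 2,
                                r$y_origin - r$cell / 2)),
             world_file_path(path))
}

read_world_file <- function(path) {
  wf <- world_file_path(path)
  if (!file.exists(wf)) return(NULL)
  v <- as.numeric(readLines(wf, n = 6L))
  if (v[2] != 0 || v[3] != 0 || v[1] <= 0 || v[4] >= 0)
    stop("format error: rotated or flipped world file unsupported: ", wf,
         call. = FALSE)
  list(cell = v[1], origin = c(v[5] - v[1] / 2, v[6] + v[1] / 2))
}

sidecar_path <- function(path) paste0(path, ".json")

## ---- public I/O ----

#' Load a georeferenced raster
#'
#' Supported formats: ESRI ASCII grid (`.asc`) for single-band rasters
#' (height, label, scalar), TIFF (`.tif`/`.tiff`) with an ESRI world file
#' (`.tfw`) for RGB orthomosaics and 8-bit label masks, and PNG (`.png`) for
#' label masks. PNG and TIFF georeference comes from the world file or, if
#' absent, from `transform` (e.g. a paired raster's georeference).
#'
#' @param path file path
#' @param expected_meaning one of `"rgb"`, `"height"`, `"label"`, `"scalar"`;
#'   the band count and value domain are validated against it.
#' @param transform optional `reef_raster` (or list with `origin`, `cell`)
#'   supplying the georeference for formats that carry none.
#' @return a [reef_raster()]
#' @export
load_raster <- function(path, expected_meaning = c("scalar", "rgb", "height", "label"),
                        transform = NULL) {
  expected_meaning <- match.arg(expected_meaning)
  if (!file.exists(path)) stop("I/O error: file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "asc") {
    if (expected_meaning == "rgb")
      stop("format error: ASCII grid is single-band; expected rgb", call. = FALSE)
    g <- read_ascii_grid(path)
    return(reef_raster(g$data, origin = g$origin, cell = g$cell,
                       meaning = expected_meaning,
                       nodata = if (is.null(g$nodata)) default_nodata(expected_meaning)
                                else g$nodata))
  }
  if (!ext %in% c("tif", "tiff", "png"))
    stop("format error: unsupported raster format: .", ext, call. = FALSE)
  img <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  sc <- sidecar_path(path)
  meta <- if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else NULL
  geo <- read_world_file(path)
  if (is.null(geo) && !is.null(transform))
    geo <- list(cell = transform$cell,
                origin = c(transform$x_origin, transform$y_origin))
  if (is.null(geo))
    stop("format error: no world file and no transform given for ", path,
         call. = FALSE)
  nbands <- if (length(dim(img)) == 3L) dim(img)[3] else 1L
  nodata <- if (!is.null(meta$nodata)) meta$nodata else default_nodata(expected_meaning)
  if (expected_meaning == "rgb") {
    if (nbands < 3L)
      stop("format error: expected 3 bands for rgb, found ", nbands, call. = FALSE)
    dat <- round(img[, , 1:3, drop = FALSE] * 255)
  } else {
    if (nbands != 1L && !(nbands %in% c(2L, 4L)))  # allow alpha channel, drop it
      stop("format error: expected 1 band for ", expected_meaning,
           ", found ", nbands, call. = FALSE)
    dat <- if (length(dim(img)) == 3L) img[, , 1] else img
    dat <- round(dat * 255)
    dat[dat == nodata] <- NA
    if (expected_meaning == "label" && !all(dat[!is.na(dat)] %in% c(0, 1, 2)))
      stop("format error: label raster contains values outside {0, 1, 2}",
           call. = FALSE)
  }
  reef_raster(dat, origin = geo$origin, cell = geo$cell,
              meaning = expected_meaning, nodata = nodata)
}

#' Save a georeferenced raster
#'
#' Single-band rasters are written as ESRI ASCII grids (`.asc`), which
#' round-trip values exactly and embed the georeference and nodata sentinel.
#' RGB and label rasters may be written as TIFF/PNG; these get an ESRI world
#' file plus a small JSON sidecar recording the nodata sentinel and band
#' meaning.
#'
#' @param r a [reef_raster()]
#' @param path destination; extension selects the format (`.asc`, `.tif`,
#'   `.png`).
#' @return invisibly `path`
#' @export
save_raster <- function(r, path) {
  stopifnot(inherits(r, "reef_raster"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "asc") {
    if (r$meaning == "rgb")
      stop("format error: ASCII grid is single-band", call. = FALSE)
    write_ascii_grid(r, path)
    return(invisible(path))
  }
  if (!ext %in% c("tif", "tiff", "png"))
    stop("format error: unsupported raster format: .", ext, call. = FALSE)
  if (r$meaning %in% c("height", "scalar"))
    stop("format error: write float rasters as .asc, not .", ext, call. = FALSE)
  if (r$meaning == "rgb") {
    img <- r$data / 255
    img[is.na(img)] <- 0
  } else {
    m <- r$data
    m[is.na(m)] <- r$nodata
    img <- m / 255
  }
  if (ext == "png") png::writePNG(img, path)
  else tiff::writeTIFF(img, path, bits.per.sample = 8L)
  write_world_file(r, path)
  jsonlite::write_json(list(nodata = r$nodata, meaning = r$meaning,
                            cell = r$cell,
                            origin = c(r$x_origin, r$y_origin)),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
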
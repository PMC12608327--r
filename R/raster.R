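#' Georeferenced single-band raster grid
#'
#' Minimal raster container used for the DSM, DTM and CHM. Cells are square
#' with side `res`; `origin` is the x/y of the top-left *corner* of the grid;
#' cell `(i, j)` (row `i` from the top, column `j` from the left, 1-based)
#' covers the half-open square starting at
#' `(origin[1] + (j-1)*res, origin[2] - i*res)` and its value is sampled at
#' the cell center. `NA` marks no-data.
#'
#' @param values numeric matrix (rows = north to south).
#' @param origin numeric `c(x, y)` of the top-left corner.
#' @param res cell size in meters (> 0).
#' @param crs CRS identifier.
#' @return a `raster_grid` object.
#' @export
raster_grid <- function(values, origin, res, crs = "local") {
  stopifnot(is.matrix(values), length(origin) == 2, res > 0)
  structure(list(values = values, origin = as.numeric(origin),
                 res = as.numeric(res), crs = crs),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d x %d cells @ %.2f m, origin (%.2f, %.2f)\n",
              nrow(v), ncol(v), x$res, x$origin[1], x$origin[2]))
  ok <- !is.na(v)
  if (any(ok))
    cat(sprintf("  values: [%.3f, %.3f], %.1f%% NA\n",
                min(v[ok]), max(v[ok]), 100 * mean(!ok)))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Grid specification snapped to a resolution-aligned origin
#'
#' Builds the cell layout covering a bounding box, with the origin snapped to
#' a multiple of `res`. Snapping forces rasters built at different epochs
#' over the same area onto one common grid, so canopy models are cellwise
#' comparable.
#'
#' @param bbox named numeric `c(xmin, xmax, ymin, ymax)`.
#' @param res cell size (m); the study default is 0.5 m, with 1 m supported.
#' @param crs CRS identifier.
#' @return an empty (all-`NA`) [raster_grid()] covering `bbox`.
#' @export
grid_for_bbox <- function(bbox, res = 0.5, crs = "local") {
  stopifnot(res > 0, bbox["xmax"] >= bbox["xmin"], bbox["ymax"] >= bbox["ymin"])
  x0 <- floor(bbox[["xmin"]] / res) * res
  y1 <- ceiling(bbox[["ymax"]] / res) * res
  nc <- max(1L, as.integer(ceiling((bbox[["xmax"]] - x0) / res - 1e-9)))
  nr <- max(1L, as.integer(ceiling((y1 - bbox[["ymin"]]) / res - 1e-9)))
  raster_grid(matrix(NA_real_, nr, nc), origin = c(x0, y1), res = res,
              crs = crs)
}

#' Cell-center coordinates of a raster grid
#'
#' @param grid a [raster_grid()].
#' @return list with numeric vectors `x` (length ncol) and `y` (length nrow,
#'   north to south).
#' @export
cell_centers <- function(grid) {
  d <- dim(grid$values)
  list(x = grid$origin[1] + (seq_len(d[2]) - 0.5) * grid$res,
       y = grid$origin[2] - (seq_len(d[1]) - 0.5) * grid$res)
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$res, b$res, tolerance = 1e-12))
}

#' Read / write rasters as ESRI ASCII grids
#'
#' Plain-text raster exchange (`.asc`): a 6-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `nodata_value`)
#' followed by rows of values, north first. `NA` maps to the nodata value.
#'
#' @param grid a [raster_grid()].
#' @param path file path.
#' @param nodata numeric used to encode `NA` on disk.
#' @return `write_asc` returns `path` invisibly; `read_asc` returns a
#'   [raster_grid()].
#' @export
write_asc <- function(grid, path, nodata = -9999) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  yll <- grid$origin[2] - nr * grid$res
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", grid$origin[1]),
           sprintf("yllcorner %.10g", yll),
           sprintf("cellsize %.10g", grid$res),
           sprintf("nodata_value %.10g", nodata))
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(format(v, trim = TRUE, digits = 10), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_asc
#' @param crs CRS identifier to attach on read.
#' @export
read_asc <- function(path, crs = "local") {
  lines <- readLines(path, n = 6)
  kv <- strsplit(trimws(lines), "\\s+")
  hdr <- setNames(as.numeric(vapply(kv, `[`, "", 2)),
                  tolower(vapply(kv, `[`, "", 1)))
  v <- as.matrix(read.table(path, skip = 6))
  dimnames(v) <- NULL
  v[v == hdr[["nodata_value"]]] <- NA_real_
  raster_grid(v,
              origin = c(hdr[["xllcorner"]],
                         hdr[["yllcorner"]] + hdr[["nrows"]] * hdr[["cellsize"]]),
              res = hdr[["cellsize"]], crs = crs)
}
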
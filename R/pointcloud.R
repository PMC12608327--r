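#' Classified LiDAR point clouds
#'
#' A `point_cloud` is a [data.table::data.table] with one row per return and
#' columns `x`, `y`, `z` (projected meters), `return_number`,
#' `number_of_returns` and `class_code` (ASPRS classification code), plus
#' attributes `crs` (identifier string) and `epoch` (date tag). Row order
#' carries no meaning: the cloud is an unordered multiset of returns.
#'
#' Recognized class codes follow the ASPRS convention used in national ALS
#' archives: 0 unclassified, 2 ground, 3 low vegetation (0-0.40 m), 4 medium
#' vegetation (0.40-2.00 m), 5 tall vegetation (above 2.00 m), 6 buildings,
#' 7 noise, 8 water, 12 overlap.
#'
#' @param points data.frame with columns `x`, `y`, `z`, `return_number`,
#'   `number_of_returns`, `class_code` (missing ancillary columns default to
#'   single-return ground-free records).
#' @param crs coordinate reference system identifier; must be a projected
#'   (metric) CRS.
#' @param epoch free-form date tag, e.g. `"2013"`.
#' @return a `point_cloud` object.
#' @export
point_cloud <- function(points, crs = "local", epoch = NA_character_) {
  pts <- as.data.table(points)
  if (!all(c("x", "y", "z") %in% names(pts)))
    stop("point cloud needs x, y, z columns")
  if (is.null(pts$return_number)) pts[, return_number := 1L]
  if (is.null(pts$number_of_returns)) pts[, number_of_returns := 1L]
  if (is.null(pts$class_code)) {
    warning("missing classification; assigning class 0 (unclassified)")
    pts[, class_code := 0L]
  }
  pts[, return_number := as.integer(return_number)]
  pts[, number_of_returns := as.integer(number_of_returns)]
  pts[, class_code := as.integer(class_code)]
  if (nrow(pts) && any(pts$return_number < 1L |
                       pts$return_number > pts$number_of_returns))
    stop("return_number must lie in [1, number_of_returns]")
  valid <- c(0L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 12L)
  if (nrow(pts) && any(!pts$class_code %in% valid))
    stop("unrecognized class codes: ",
         paste(setdiff(unique(pts$class_code), valid), collapse = ", "))
  setattr(pts, "crs", crs)
  setattr(pts, "epoch", epoch)
  setattr(pts, "class", c("point_cloud", class(pts)))
  pts[]
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d returns, crs '%s', epoch '%s'\n",
              nrow(x), attr(x, "crs"), attr(x, "epoch")))
  if (nrow(x)) {
    bb <- cloud_bbox(x)
    cat(sprintf("  extent: x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
                bb["xmin"], bb["xmax"], bb["ymin"], bb["ymax"],
                min(x$z), max(x$z)))
    cat("  classes:", paste(sort(unique(x$class_code)), collapse = " "), "\n")
  }
  invisible(x)
}

#' Bounding box of a point cloud
#'
#' @param cloud a [point_cloud()].
#' @return named numeric `c(xmin, xmax, ymin, ymax)`; all-`NA` for an empty
#'   cloud.
#' @export
cloud_bbox <- function(cloud) {
  if (!nrow(cloud))
    return(c(xmin = NA_real_, xmax = NA_real_, ymin = NA_real_,
             ymax = NA_real_))
  c(xmin = min(cloud$x), xmax = max(cloud$x),
    ymin = min(cloud$y), ymax = max(cloud$y))
}

#' Read a point cloud from the plain-text exchange format
#'
#' The package's text dialect is a whitespace-separated table with a single
#' header line and columns `x y z return_number number_of_returns class_code`
#' in that order (extra columns are ignored). It is a lossless stand-in for
#' binary LAS tiles in tests and examples; production LAS/LAZ files can be
#' converted to it with any LAS tool chain.
#'
#' @param path file path.
#' @inheritParams point_cloud
#' @return a [point_cloud()]. An empty file (header only, or zero bytes)
#'   yields an empty cloud rather than an error.
#' @export
read_cloud <- function(path, crs = "local", epoch = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0)
    return(point_cloud(data.table(x = numeric(), y = numeric(),
                                  z = numeric(), return_number = integer(),
                                  number_of_returns = integer(),
                                  class_code = integer()),
                       crs = crs, epoch = epoch))
  tab <- tryCatch(
    fread(path, header = TRUE),
    error = function(e) stop("malformed point file '", path, "': ",
                             conditionMessage(e)))
  need <- c("x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("malformed point file '", path, "': missing columns ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  point_cloud(tab, crs = crs, epoch = epoch)
}

#' Write a point cloud in the plain-text exchange format
#'
#' @param cloud a [point_cloud()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path) {
  cols <- c("x", "y", "z", "return_number", "number_of_returns", "class_code")
  fwrite(as.data.table(cloud)[, cols, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' Merge point-cloud tiles
#'
#' Concatenates the records of several tiles into one cloud covering their
#' union. Duplicate points in overlap areas are retained; overlap handling is
#' a class-filtering concern (class 12) downstream.
#'
#' @param clouds list of [point_cloud()] objects sharing one CRS.
#' @return merged [point_cloud()]; the epoch tag is kept when the tiles agree
#'   on it.
#' @export
merge_tiles <- function(clouds) {
  stopifnot(length(clouds) >= 1)
  crs <- unique(vapply(clouds, attr, "", which = "crs"))
  if (length(crs) != 1)
    stop("cannot merge tiles with different CRS: ",
         paste(crs, collapse = " vs "))
  epochs <- unique(vapply(clouds, function(cl)
    as.character(attr(cl, "epoch") %||% NA_character_), ""))
  epoch <- if (length(epochs) == 1) epochs else NA_character_
  merged <- rbindlist(lapply(clouds, as.data.table), use.names = TRUE)
  point_cloud(merged, crs = crs, epoch = epoch)
}

#' Filter a cloud by classification code
#'
#' Drops returns whose class is in `drop_codes`. The default drop set
#' \{0, 7, 8, 12\} removes unclassified points, noise, water and
#' multi-overlap points, the four categories rejected before surface
#' modelling.
#'
#' @param cloud a [point_cloud()].
#' @param drop_codes integer vector of class codes to remove.
#' @return filtered [point_cloud()]; an all-dropped cloud is returned empty
#'   with a warning.
#' @export
filter_classes <- function(cloud, drop_codes = c(0L, 7L, 8L, 12L)) {
  keep <- !(cloud$class_code %in% as.integer(drop_codes))
  out <- point_cloud(as.data.table(cloud)[keep],
                     crs = attr(cloud, "crs"), epoch = attr(cloud, "epoch"))
  if (nrow(cloud) && !nrow(out))
    warning("class filter removed every return")
  out
}
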
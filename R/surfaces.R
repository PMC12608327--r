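#' Rasterize scattered elevations through a Delaunay TIN
#'
#' Builds the Delaunay triangulation of `(x, y)` and evaluates its piecewise
#' linear interpolant at every cell center of `grid`. Cell centers outside
#' the convex hull of the points are `NA`: the TIN never extrapolates.
#' Because the interpolant is linear on each triangle, any affine field
#' `z = a*x + b*y + c` sampled at the input points is reproduced exactly
#' (to machine precision) at all interior cells, whichever triangulation of
#' cocircular point sets is produced.
#'
#' @param points data.frame with columns `x`, `y`, `z` (>= 3 non-collinear
#'   rows).
#' @param grid a [raster_grid()] giving the target layout (values ignored).
#' @return `grid` with interpolated values.
#' @export
build_tin_raster <- function(points, grid) {
  pts <- as.data.frame(points)
  if (nrow(pts) < 3)
    stop("TIN interpolation needs at least 3 points")
  cc <- cell_centers(grid)
  d <- dim(grid$values)
  qx <- rep(cc$x, each = d[1])
  qy <- rep(cc$y, times = d[2])
  z <- .cpp_tin_interpolate(pts$x, pts$y, pts$z, qx, qy)
  grid$values <- matrix(z, nrow = d[1], ncol = d[2])
  grid
}

#' Digital surface and terrain models from a classified cloud
#'
#' `make_dsm()` interpolates the *first* returns (canopy surface);
#' `make_dtm()` interpolates the ground: classified ground returns (class 2)
#' when present, otherwise the farthest returns
#' (`return_number == number_of_returns`) with a warning. Both use
#' Delaunay-TIN linear interpolation at resolution `res` (default 0.5 m; 1 m
#' is the supported coarse alternative) on a resolution-snapped grid so that
#' rasters from different epochs align cellwise.
#'
#' @param cloud a class-filtered [point_cloud()].
#' @param res cell size in m.
#' @param grid optional [raster_grid()] to interpolate onto (overrides
#'   `res`); pass the DSM's grid when building the DTM to guarantee identical
#'   geometry.
#' @return a [raster_grid()].
#' @export
make_dsm <- function(cloud, res = 0.5, grid = NULL) {
  sel <- cloud$return_number == 1L
  if (!any(sel)) stop("no first returns in cloud")
  if (is.null(grid)) grid <- grid_for_bbox(cloud_bbox(cloud), res = res,
                                           crs = attr(cloud, "crs"))
  build_tin_raster(as.data.table(cloud)[sel, .(x, y, z)], grid)
}

#' @rdname make_dsm
#' @export
make_dtm <- function(cloud, res = 0.5, grid = NULL) {
  sel <- cloud$class_code == 2L
  if (!any(sel)) {
    warning("no classified ground returns (class 2); ",
            "falling back to farthest returns")
    sel <- cloud$return_number == cloud$number_of_returns
  }
  if (!any(sel)) stop("no qualifying ground returns in cloud")
  if (is.null(grid)) grid <- grid_for_bbox(cloud_bbox(cloud), res = res,
                                           crs = attr(cloud, "crs"))
  build_tin_raster(as.data.table(cloud)[sel, .(x, y, z)], grid)
}

#' Canopy height model as the DSM - DTM difference
#'
#' Cellwise difference on identical grid geometry. `NA` in either input
#' propagates. Small negative differences arise from vertical noise where
#' there is no canopy; they are clamped to 0 so that the later height mask
#' does not turn noisy open ground into spurious no-data.
#'
#' @param dsm,dtm [raster_grid()]s with identical geometry.
#' @param clamp_negative clamp negative cells to 0 (default `TRUE`).
#' @return CHM [raster_grid()].
#' @export
compute_chm <- function(dsm, dtm, clamp_negative = TRUE) {
  if (!same_geometry(dsm, dtm))
    stop("DSM and DTM grids differ in geometry")
  v <- dsm$values - dtm$values
  if (clamp_negative) v[!is.na(v) & v < 0] <- 0
  raster_grid(v, origin = dsm$origin, res = dsm$res, crs = dsm$crs)
}

#' 3x3 Gaussian kernel used to smooth the CHM
#'
#' Weights (rows x cols): 0.0625 0.125 0.0625 / 0.125 0.25 0.125 /
#' 0.0625 0.125 0.0625. They sum to 1 and are symmetric under 90-degree
#' rotation, so a constant raster is preserved exactly.
#'
#' @return 3x3 numeric matrix.
#' @export
smoothing_kernel <- function() {
  matrix(c(0.0625, 0.125, 0.0625,
           0.125,  0.25,  0.125,
           0.0625, 0.125, 0.0625), 3, 3, byrow = TRUE)
}

#' Gaussian smoothing of a raster
#'
#' Centered 3x3 convolution with [smoothing_kernel()]. The filter is
#' NA-aware: at border cells and next to no-data cells the weights over the
#' valid neighbors are renormalized to sum to 1 (no padding), which avoids
#' biasing stand edges downward. A cell whose whole 3x3 neighborhood is `NA`
#' stays `NA`. Output values never leave the `[min, max]` range of the input.
#'
#' @param grid a [raster_grid()].
#' @param kernel 3x3 weight matrix summing to 1.
#' @return smoothed [raster_grid()].
#' @export
gaussian_smooth <- function(grid, kernel = smoothing_kernel()) {
  stopifnot(all(dim(kernel) == c(3, 3)))
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  ok <- !is.na(v)
  vz <- ifelse(ok, v, 0)
  acc <- matrix(0, nr, nc)
  wacc <- matrix(0, nr, nc)
  for (di in -1:1) {
    for (dj in -1:1) {
      w <- kernel[di + 2, dj + 2]
      sr <- max(1, 1 + di):min(nr, nr + di)   # destination rows
      sc <- max(1, 1 + dj):min(nc, nc + dj)
      acc[sr, sc] <- acc[sr, sc] + w * vz[sr - di, sc - dj, drop = FALSE]
      wacc[sr, sc] <- wacc[sr, sc] + w * ok[sr - di, sc - dj, drop = FALSE]
    }
  }
  out <- ifelse(wacc > 0, acc / wacc, NA_real_)
  raster_grid(out, origin = grid$origin, res = grid$res, crs = grid$crs)
}

#' Mask low canopy out of a CHM
#'
#' Cells lower than `threshold` become `NA`; cells at or above it are kept
#' unchanged. The study default of 7 m removes young growth and understorey
#' before tree-top detection; the boundary value itself (exactly 7 m) is
#' retained.
#'
#' @param grid a [raster_grid()].
#' @param threshold height threshold in m (> 0).
#' @return masked [raster_grid()].
#' @export
mask_below <- function(grid, threshold = 7) {
  stopifnot(threshold > 0)
  v <- grid$values
  v[!is.na(v) & v < threshold] <- NA_real_
  raster_grid(v, origin = grid$origin, res = grid$res, crs = grid$crs)
}
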
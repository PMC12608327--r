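test_that("TIN rasterization reproduces affine fields exactly", {
  g <- grid_for_bbox(c(xmin = 0, xmax = 10, ymin = 0, ymax = 10), res = 0.5)
  cc <- cell_centers(g)
  plane <- function(x, y) 2 * x + 3 * y + 1
  truth <- outer(cc$y * 3, cc$x * 2, "+") + 1

  set.seed(2)
  pts <- data.frame(x = runif(300, 0, 10), y = runif(300, 0, 10))
  pts$z <- plane(pts$x, pts$y)
  r <- build_tin_raster(pts, g)
  expect_lt(max(abs(r$values - truth), na.rm = TRUE), 1e-9)

  # regular (cocircular) grid: still exact whatever the tie-breaking
  gp <- expand.grid(x = 0:10, y = 0:10)
  gp$z <- plane(gp$x, gp$y)
  r2 <- build_tin_raster(gp, g)
  expect_false(anyNA(r2$values))
  expect_lt(max(abs(r2$values - truth)), 1e-9)
})

test_that("single triangle interpolates barycentrically; hull is strict", {
  # triangle (0,0,z=0), (4,0,z=8), (0,4,z=4); query the centroid cell
  tri <- data.frame(x = c(0, 4, 0), y = c(0, 0, 4), z = c(0, 8, 4))
  g <- raster_grid(matrix(NA_real_, 1, 1), origin = c(1. - 1 / 3, 1 + 2 / 3),
                   res = 1)  # single cell centered near the centroid
  cc <- cell_centers(g)
  # hand barycentric value at that center
  l <- function(px, py) {
    a <- cbind(c(4 - 0, 0 - 0), c(0 - 0, 4 - 0))
    w <- solve(a, c(px - 0, py - 0))
    c(1 - sum(w), w)
  }
  w <- l(cc$x, cc$y)
  expected <- sum(w * tri$z)
  r <- build_tin_raster(tri, g)
  expect_equal(r$values[1, 1], expected, tolerance = 1e-12)

  # a cell outside the convex hull is NA
  gout <- raster_grid(matrix(NA_real_, 1, 1), origin = c(3.5, 4), res = 1)
  expect_true(is.na(build_tin_raster(tri, gout)$values[1, 1]))
})

test_that("TIN refuses degenerate inputs", {
  g <- grid_for_bbox(c(xmin = 0, xmax = 1, ymin = 0, ymax = 1), res = 0.5)
  expect_error(build_tin_raster(data.frame(x = 1:2, y = 1:2, z = 1:2), g),
               "at least 3")
  coll <- data.frame(x = 1:5, y = 2 * (1:5), z = 1:5)
  expect_error(build_tin_raster(coll, g), "collinear")
})

test_that("DSM/DTM source selection and the treeless identity", {
  cfg <- small_config(vertical_noise_sd = 0)
  terrain <- generate_terrain(cfg)
  empty <- data.table(id = integer(), x = numeric(), y = numeric(),
                      apex_height = numeric(), crown_radius = numeric(),
                      species = character(), unit_id = character())
  cl <- simulate_point_cloud(empty, terrain, cfg, seed = 12)
  grid <- grid_for_bbox(cloud_bbox(cl), res = 0.5)
  dsm <- make_dsm(cl, grid = grid)
  dtm <- make_dtm(cl, grid = grid)
  expect_equal(dsm$values, dtm$values, tolerance = 1e-12)
  chm <- compute_chm(dsm, dtm)
  expect_true(all(chm$values[!is.na(chm$values)] == 0))

  # fallback to farthest returns when class 2 is absent
  cl2 <- point_cloud(data.table(x = c(0, 5, 0, 5, 2), y = c(0, 0, 5, 5, 2),
                                z = c(1, 1, 1, 1, 10),
                                return_number = c(2L, 2L, 2L, 2L, 1L),
                                number_of_returns = 2L,
                                class_code = 5L))
  expect_warning(d <- make_dtm(cl2, res = 1), "farthest returns")
  expect_equal(max(d$values, na.rm = TRUE), 1)
})

test_that("a 20 m synthetic tree yields a CHM peak within the cone bound", {
  cfg <- small_config(vertical_noise_sd = 0)
  terrain <- generate_terrain(cfg)
  tree <- data.table(id = 1L, x = 25, y = 25, apex_height = 20,
                     crown_radius = 3, species = "pine", unit_id = "U001")
  cl <- simulate_point_cloud(tree, terrain, cfg, seed = 5)
  grid <- grid_for_bbox(cloud_bbox(cl), res = 0.5)
  chm <- compute_chm(make_dsm(cl, grid = grid), make_dtm(cl, grid = grid))
  # geometric oracle: the cone falls depth_frac*h/crown_r = 3 m per meter
  # off-apex; the nearest jittered pulse is at most s*sqrt(2) from the apex
  # and the apex cell center at most one further pulse spacing away
  s <- 1 / sqrt(cfg$pulse_density)
  slope <- cfg$crown_depth_frac * 20 / 3
  peak <- max(chm$values, na.rm = TRUE)
  expect_lte(peak, 20)
  expect_gte(peak, 20 - slope * 2 * s)
})

test_that("CHM differencing: subtraction, NA propagation, clamping", {
  mk <- function(v) raster_grid(matrix(v, 2, 2), origin = c(0, 2), res = 1)
  dsm <- mk(c(22, 1.9, NA, 5))
  dtm <- mk(c(2, 2, 2, NA))
  chm <- compute_chm(dsm, dtm)
  expect_equal(chm$values[1, 1], 20)
  expect_equal(chm$values[2, 1], 0)      # 1.9 - 2.0 clamped
  expect_true(is.na(chm$values[1, 2]))
  expect_true(is.na(chm$values[2, 2]))
  expect_equal(compute_chm(dsm, dtm, clamp_negative = FALSE)$values[2, 1],
               -0.1, tolerance = 1e-12)
  bad <- raster_grid(matrix(0, 3, 2), origin = c(0, 3), res = 1)
  expect_error(compute_chm(dsm, bad), "geometry")
})

test_that("Gaussian smoothing: kernel response, constants, bounds", {
  k <- smoothing_kernel()
  expect_equal(sum(k), 1)
  expect_equal(k, t(k))
  expect_equal(k, k[3:1, 3:1])

  v <- matrix(0, 9, 9); v[5, 5] <- 16
  sm <- gaussian_smooth(raster_grid(v, c(0, 9), 1))
  expect_equal(sm$values[5, 5], 4)
  expect_equal(sm$values[5, 6], 2)
  expect_equal(sm$values[4, 4], 1)

  # constants survive exactly, including at borders (renormalization)
  const <- gaussian_smooth(raster_grid(matrix(10, 7, 5), c(0, 7), 1))
  expect_equal(const$values, matrix(10, 7, 5), tolerance = 1e-12)

  set.seed(9)
  r <- raster_grid(matrix(runif(400, 5, 30), 20, 20), c(0, 20), 1)
  s <- gaussian_smooth(r)
  expect_gte(min(s$values), min(r$values))
  expect_lte(max(s$values), max(r$values))
  # interior mean is preserved to first order on a constant-extended field
  pad <- raster_grid(matrix(13.5, 12, 12), c(0, 12), 1)
  expect_equal(mean(gaussian_smooth(pad)$values), 13.5, tolerance = 1e-9)

  allna <- gaussian_smooth(raster_grid(matrix(NA_real_, 3, 3), c(0, 3), 1))
  expect_true(all(is.na(allna$values)))
})

test_that("height mask keeps the boundary and drops below-threshold cells", {
  v <- matrix(c(6.99, 7, 7.01, 12), 2, 2)
  m <- mask_below(raster_grid(v, c(0, 2), 1), 7)
  expect_true(is.na(m$values[1, 1]))
  expect_equal(m$values[2, 1], 7)
  expect_equal(m$values[1, 2], 7.01)
  all_high <- raster_grid(matrix(9, 3, 3), c(0, 3), 1)
  expect_equal(mask_below(all_high)$values, all_high$values)
  expect_error(mask_below(all_high, 0), "threshold")
})

test_that("ASCII grid IO round-trips values, geometry and NA", {
  v <- matrix(c(1.5, NA, 3, 4.25, 5, NA), 2, 3)
  g <- raster_grid(v, origin = c(100, 250), res = 0.5, crs = "EPSG:2180")
  path <- withr::local_tempfile(fileext = ".asc")
  write_asc(g, path)
  back <- read_asc(path, crs = "EPSG:2180")
  expect_equal(back$values, v)
  expect_equal(back$origin, g$origin)
  expect_equal(back$res, g$res)
})

test_that("epoch grids snap onto one lattice", {
  a <- grid_for_bbox(c(xmin = 0.3, xmax = 10.2, ymin = 0.1, ymax = 9.8),
                     res = 0.5)
  b <- grid_for_bbox(c(xmin = 0.1, xmax = 10.4, ymin = 0.4, ymax = 9.6),
                     res = 0.5)
  expect_equal(a$origin[1] %% 0.5, 0)
  expect_equal(b$origin[1] %% 0.5, 0)
  expect_equal((a$origin - b$origin) %% 0.5, c(0, 0))
})
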
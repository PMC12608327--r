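library(data.table)

# small scene used across generator tests: 1 unit of 50 x 50 m, flat terrain
small_config <- function(...) {
  defaults <- list(extent = c(xmin = 0, xmax = 50, ymin = 0, ymax = 50),
                   relief_amplitude = 0, n_neas = 0, seed = 7L)
  do.call(scene_config, utils::modifyList(defaults, list(...)))
}

square_ring <- function(x0 = 0, y0 = 0, side = 10)
  cbind(c(x0, x0 + side, x0 + side, x0),
        c(y0, y0, y0 + side, y0 + side))

one_unit <- function(ring = square_ring(side = 100), address = "U001",
                     species = "pine", mean_height = 18,
                     crs = "local") {
  forest_units(data.table(forest_address = address,
                          dominant_species = species,
                          site_type = "FPF", age = 60,
                          true_mean_height = mean_height,
                          growth_rate = 0.25,
                          land_kind = "stand"),
               list(ring), crs = crs)
}

# independent brute-force oracle for the variable-window maxima contract:
# compare every cell against every cell within its own radius, same
# lexicographic tie-break as documented
brute_force_tops <- function(values, res, slope = 0.16, intercept = 0.8) {
  nr <- nrow(values); nc <- ncol(values)
  hits <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- values[i, j]
    if (is.na(v)) next
    radius <- slope * v + intercept
    rc <- ceiling(radius / res)
    top <- TRUE
    for (ii in max(1, i - rc):min(nr, i + rc)) {
      for (jj in max(1, j - rc):min(nc, j + rc)) {
        if (ii == i && jj == j) next
        nv <- values[ii, jj]
        if (is.na(nv)) next
        if (((ii - i) * res)^2 + ((jj - j) * res)^2 > radius^2 + 1e-9) next
        if (nv > v || (nv == v && (ii < i || (ii == i && jj < j)))) {
          top <- FALSE
          break
        }
      }
      if (!top) break
    }
    if (top) hits <- rbind(hits, c(i, j))
  }
  hits
}

# random masked CHM-like raster for property tests
random_chm <- function(nr, nc, seed, res = 0.5) {
  set.seed(seed)
  v <- matrix(NA_real_, nr, nc)
  n_blobs <- 25
  ci <- sample(nr, n_blobs, TRUE)
  cj <- sample(nc, n_blobs, TRUE)
  h <- runif(n_blobs, 8, 28)
  for (k in seq_len(n_blobs)) {
    for (i in max(1, ci[k] - 6):min(nr, ci[k] + 6))
      for (j in max(1, cj[k] - 6):min(nc, cj[k] + 6)) {
        d <- sqrt((i - ci[k])^2 + (j - cj[k])^2) * res
        val <- h[k] - 3 * d
        if (val >= 7 && (is.na(v[i, j]) || val > v[i, j])) v[i, j] <- val
      }
  }
  raster_grid(v, origin = c(0, nr * res), res = res)
}
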
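#' Configuration of a synthetic two-epoch forest scene
#'
#' Bundles every knob of the synthetic-forest generator. The defaults state
#' the acquisition and stand conditions the analysis pipeline assumes:
#' pulse density 4 pts/m2 and vertical noise sd 0.2 m (the middle of the
#' 0.15-0.25 m accuracy band of national ALS archives), pine-dominated
#' species shares, mature stand heights, nine growing seasons between
#' epochs, inventories of ~10 representative trees with a 0.3 m per-tree
#' error recorded in whole meters.
#'
#' @param extent named numeric `c(xmin, xmax, ymin, ymax)` in m.
#' @param pulse_density laser pulses per m2 (> 0).
#' @param vertical_noise_sd Gaussian vertical noise sd in m (0.05-0.5).
#' @param noise_fraction fraction of returns duplicated as class-7 noise
#'   points (default 0).
#' @param stem_density trees per ha.
#' @param relief_amplitude,relief_length amplitude (m) and correlation
#'   length (m) of the smooth synthetic terrain.
#' @param species_probs named probabilities of the dominant species of a
#'   unit; defaults follow the Scots-pine-dominated share structure of
#'   northern-Poland outwash-plain forests.
#' @param minority_fraction within-unit share of trees not of the dominant
#'   species.
#' @param height_range range (m) the per-unit mean tree height of the first
#'   epoch is drawn from.
#' @param height_sd within-unit tree height sd (m).
#' @param growth_rate_range range (m/yr) the per-unit annual height growth
#'   is drawn from; the default 0.05-0.45 m/yr spans slow water-stressed
#'   alder stands to fast young pine, giving 0.5-4 m increments over the
#'   default nine years.
#' @param growth_jitter_sd per-tree growth jitter sd over the whole period
#'   (m).
#' @param years growing seasons between the epochs.
#' @param epochs character tags of the two epochs.
#' @param crown_slope,crown_intercept crown radius model
#'   `radius = slope * height + intercept` (m).
#' @param crown_depth_frac crown depth as a fraction of tree height.
#' @param n_sample trees measured per unit in the synthetic inventory.
#' @param inventory_noise_sd per-tree inventory height error sd (m).
#' @param leaf_off_bias downward bias (m) on first returns from deciduous
#'   crowns, emulating leaf-off acquisitions; default 0 (off).
#' @param n_neas number of small non-exclusive areas (taller residual-tree
#'   clusters) inserted into the scene.
#' @param seed integer RNG seed; a fixed seed makes every generated
#'   artifact byte-identical across runs.
#' @return a `scene_config` list.
#' @export
scene_config <- function(extent = c(xmin = 0, xmax = 200, ymin = 0, ymax = 200),
                         pulse_density = 4,
                         vertical_noise_sd = 0.2,
                         noise_fraction = 0,
                         stem_density = 400,
                         relief_amplitude = 3,
                         relief_length = 60,
                         species_probs = c(pine = 0.967, alder = 0.017,
                                           birch = 0.007, spruce = 0.003,
                                           larch = 0.001),
                         minority_fraction = 0.1,
                         height_range = c(12, 24),
                         height_sd = 1.2,
                         growth_rate_range = c(0.05, 0.45),
                         growth_jitter_sd = 0.2,
                         years = 9,
                         epochs = c("2013", "2022"),
                         crown_slope = 0.10,
                         crown_intercept = 0.5,
                         crown_depth_frac = 0.45,
                         n_sample = 10,
                         inventory_noise_sd = 0.3,
                         leaf_off_bias = 0,
                         n_neas = 2,
                         seed = 1L) {
  if (extent[["xmax"]] <= extent[["xmin"]] ||
      extent[["ymax"]] <= extent[["ymin"]])
    stop("invalid scene config: empty extent")
  if (pulse_density <= 0) stop("invalid scene config: pulse_density <= 0")
  if (vertical_noise_sd < 0.05 - 1e-12 || vertical_noise_sd > 0.5 + 1e-12) {
    if (vertical_noise_sd != 0)  # exactly 0 allowed for geometric oracles
      stop("invalid scene config: vertical_noise_sd outside [0.05, 0.5]")
  }
  cfg <- list(extent = extent, pulse_density = pulse_density,
              vertical_noise_sd = vertical_noise_sd,
              noise_fraction = noise_fraction,
              stem_density = stem_density,
              relief_amplitude = relief_amplitude,
              relief_length = relief_length,
              species_probs = species_probs / sum(species_probs),
              minority_fraction = minority_fraction,
              height_range = height_range, height_sd = height_sd,
              growth_rate_range = growth_rate_range,
              growth_jitter_sd = growth_jitter_sd,
              years = years, epochs = epochs,
              crown_slope = crown_slope,
              crown_intercept = crown_intercept,
              crown_depth_frac = crown_depth_frac,
              n_sample = n_sample,
              inventory_noise_sd = inventory_noise_sd,
              leaf_off_bias = leaf_off_bias,
              n_neas = n_neas,
              seed = as.integer(seed))
  class(cfg) <- "scene_config"
  cfg
}

DECIDUOUS <- c("alder", "birch")

#' Smooth synthetic terrain
#'
#' A bounded, smooth random elevation field: a fixed sum of cosine waves
#' with random directions, wavelengths near `relief_length` and random
#' phases, centered and rescaled over a dense reference grid so that the
#' field's values on that grid have mean 0 and lie exactly within
#' `[-relief_amplitude, +relief_amplitude]`. A stand-in for gentle
#' outwash-plain relief. Deterministic for a fixed config seed; zero
#' amplitude yields a flat plane at 0.
#'
#' @param config a [scene_config()].
#' @return `function(x, y)` returning elevations (m), vectorized.
#' @export
generate_terrain <- function(config) {
  ext <- config$extent
  amp <- config$relief_amplitude
  if (amp == 0) return(function(x, y) rep(0, length(x)))
  K <- 12L
  par <- with_seed(config$seed, list(
    theta = runif(K, 0, 2 * pi),
    lambda = runif(K, 0.5 * config$relief_length, 1.5 * config$relief_length),
    phase = runif(K, 0, 2 * pi)))
  raw <- function(x, y) {
    g <- 0
    for (k in seq_len(K))
      g <- g + cos(2 * pi * (x * cos(par$theta[k]) + y * sin(par$theta[k])) /
                     par$lambda[k] + par$phase[k])
    g
  }
  gx <- seq(ext[["xmin"]], ext[["xmax"]], length.out = 201)
  gy <- seq(ext[["ymin"]], ext[["ymax"]], length.out = 201)
  ref <- outer(gx, gy, raw)
  ctr <- mean(ref)
  scl <- max(abs(ref - ctr))
  function(x, y) amp * (raw(x, y) - ctr) / scl
}

#' Forest-unit grid of a synthetic scene
#'
#' Splits the scene extent into an `nx` by `ny` grid of rectangular forest
#' units and draws their stand attributes: dominant species (per
#' `species_probs`), age, site type, first-epoch mean height and the
#' *true* per-unit annual growth rate. The latter two are generation truth,
#' carried as `true_mean_height` and `growth_rate` so parameter-recovery
#' checks can compare pipeline estimates against them.
#'
#' @param config a [scene_config()].
#' @param nx,ny unit grid dimensions.
#' @return a [forest_units()] layer with truth columns.
#' @export
generate_units <- function(config, nx = 4, ny = 4) {
  ext <- config$extent
  xs <- seq(ext[["xmin"]], ext[["xmax"]], length.out = nx + 1)
  ys <- seq(ext[["ymin"]], ext[["ymax"]], length.out = ny + 1)
  n <- nx * ny
  site_probs <- c(FPF = 0.5516, FMCF = 0.3934, FMHF = 0.02, MMF = 0.01,
                  TASF = 0.015, BMF = 0.005, MMCF = 0.005)
  att <- with_seed(config$seed + 1L, {
    data.table(
      forest_address = sprintf("U%03d", seq_len(n)),
      dominant_species = sample(names(config$species_probs), n, TRUE,
                                prob = config$species_probs),
      site_type = sample(names(site_probs), n, TRUE, prob = site_probs),
      age = sample(40:120, n, TRUE),
      true_mean_height = runif(n, config$height_range[1],
                               config$height_range[2]),
      growth_rate = runif(n, config$growth_rate_range[1],
                          config$growth_rate_range[2]),
      land_kind = "stand")
  })
  geoms <- vector("list", n)
  k <- 0
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      k <- k + 1
      geoms[[k]] <- cbind(c(xs[i], xs[i + 1], xs[i + 1], xs[i]),
                          c(ys[j], ys[j], ys[j + 1], ys[j + 1]))
    }
  }
  forest_units(att, geoms, crs = "local")
}

#' Trees of one synthetic stand
#'
#' Draws a Poisson number of trees (`stem_density` x unit area), scatters
#' them uniformly over the unit polygon, and assigns species (dominant with
#' probability `1 - minority_fraction`), heights (Gaussian around the
#' unit's mean, sd `height_sd`, floored at 2 m) and crown radii from the
#' linear crown model.
#'
#' @param unit one-row [forest_units()] slice (needs `geometry`,
#'   `forest_address`, `dominant_species`, `true_mean_height`).
#' @param config a [scene_config()].
#' @param seed RNG seed (default derives from the config seed).
#' @return data.table of trees: `id`, `x`, `y`, `apex_height`,
#'   `crown_radius`, `species`, `unit_id`.
#' @export
generate_stand <- function(unit, config, seed = config$seed + 10L) {
  g <- unit$geometry[[1]]
  area_ha <- poly_area(g) / 1e4
  empty <- data.table(id = integer(), x = numeric(), y = numeric(),
                      apex_height = numeric(), crown_radius = numeric(),
                      species = character(), unit_id = character())
  if (area_ha <= 0) {
    warning("degenerate (zero-area) unit polygon: empty stand")
    return(empty)
  }
  stopifnot(config$stem_density >= 0)
  with_seed(seed, {
    n <- rpois(1, config$stem_density * area_ha)
    if (n == 0) return(empty)
    bb <- c(range(g[, 1]), range(g[, 2]))
    xs <- numeric(0); ys <- numeric(0)
    while (length(xs) < n) {
      m <- 2 * (n - length(xs)) + 10
      cx <- runif(m, bb[1], bb[2])
      cy <- runif(m, bb[3], bb[4])
      keep <- point_in_polygon(cx, cy, g)
      xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
    }
    xs <- xs[seq_len(n)]; ys <- ys[seq_len(n)]
    dominant <- runif(n) >= config$minority_fraction
    minority_probs <- config$species_probs
    minority_probs[unit$dominant_species] <- 0
    sp <- rep(unit$dominant_species, n)
    if (any(!dominant) && sum(minority_probs) > 0)
      sp[!dominant] <- sample(names(minority_probs), sum(!dominant), TRUE,
                              prob = minority_probs)
    h <- pmax(2, rnorm(n, unit$true_mean_height, config$height_sd))
    data.table(id = seq_len(n), x = xs, y = ys, apex_height = h,
               crown_radius = config$crown_slope * h + config$crown_intercept,
               species = sp, unit_id = unit$forest_address)
  })
}

#' Grow a stand between epochs
#'
#' Increases every apex height by `years * rate` for the tree's species (or
#' a single shared rate), plus optional Gaussian per-tree jitter. Heights
#' never drop below 0 (dieback scenarios with negative rates are clamped);
#' positions, crowns and ownership are unchanged except that crown radii
#' track the new heights.
#'
#' @param trees data.table from [generate_stand()].
#' @param years growing seasons (>= 0).
#' @param rates single numeric rate (m/yr) or named per-species vector.
#' @param jitter_sd per-tree growth jitter sd over the whole period (m).
#' @param seed RNG seed for the jitter.
#' @param config a [scene_config()] (for the crown model).
#' @return grown tree table.
#' @export
grow_stand <- function(trees, years, rates, jitter_sd = 0, seed = NULL,
                       config = scene_config()) {
  if (years < 0) stop("invalid config: years must be >= 0")
  tr <- copy(as.data.table(trees))
  if (!nrow(tr)) return(tr)
  r <- if (length(rates) == 1 && is.null(names(rates)))
    rep(rates, nrow(tr)) else unname(rates[tr$species])
  if (anyNA(r)) stop("no growth rate for species: ",
                     paste(unique(tr$species[is.na(r)]), collapse = ", "))
  jit <- if (jitter_sd > 0)
    with_seed(seed, rnorm(nrow(tr), 0, jitter_sd)) else 0
  tr[, apex_height := pmax(0, apex_height + years * r + jit)]
  tr[, crown_radius := config$crown_slope * apex_height +
       config$crown_intercept]
  tr[]
}

#' Simulate an ALS point cloud over a synthetic stand
#'
#' Laser pulses form a jittered square grid at `pulse_density` (locally
#' uniform, as flight-line ALS delivers, rather than a pure Poisson
#' scatter). A pulse hitting a crown returns twice: a first return on the
#' crown surface (cone-shaped crowns for conifers, paraboloids for
#' deciduous trees; the highest surface wins where crowns overlap) and a
#' last return on the ground. Open-ground pulses return once from the
#' ground. All elevations get independent Gaussian noise of sd
#' `vertical_noise_sd`. Returns are classified by height above ground:
#' ground 2, vegetation 0-0.4 m class 3, 0.4-2 m class 4, above 2 m class
#' 5; a `noise_fraction` of extra class-7 points can be added. With
#' `leaf_off_bias > 0`, first returns from deciduous crowns are lowered by
#' that amount, emulating leaf-off acquisitions that see into the crown.
#'
#' @param trees tree table ([generate_stand()] rows, any number of units).
#' @param terrain elevation function from [generate_terrain()].
#' @param config a [scene_config()].
#' @param epoch epoch tag for the cloud.
#' @param seed RNG seed (default derives from the config seed).
#' @return a [point_cloud()].
#' @export
simulate_point_cloud <- function(trees, terrain, config,
                                 epoch = config$epochs[1],
                                 seed = config$seed + 1000L) {
  ext <- config$extent
  w <- ext[["xmax"]] - ext[["xmin"]]
  h <- ext[["ymax"]] - ext[["ymin"]]
  if (w <= 0 || h <= 0) stop("empty extent")
  s <- 1 / sqrt(config$pulse_density)
  nx <- max(1L, floor(w / s))
  ny <- max(1L, floor(h / s))
  with_seed(seed, {
    px <- rep(ext[["xmin"]] + (seq_len(nx) - 0.5) * s, times = ny) +
      runif(nx * ny, -s / 2, s / 2)
    py <- rep(ext[["ymin"]] + (seq_len(ny) - 0.5) * s, each = nx) +
      runif(nx * ny, -s / 2, s / 2)
    np <- nx * ny
    canopy <- rep(0, np)        # canopy surface height above ground
    hit_deciduous <- rep(FALSE, np)
    if (nrow(trees)) {
      tr <- as.data.table(trees)
      for (t in seq_len(nrow(tr))) {
        cr <- tr$crown_radius[t]
        cand <- which(abs(px - tr$x[t]) <= cr & abs(py - tr$y[t]) <= cr)
        if (!length(cand)) next
        d <- sqrt((px[cand] - tr$x[t])^2 + (py[cand] - tr$y[t])^2)
        inside <- d <= cr
        if (!any(inside)) next
        cand <- cand[inside]; d <- d[inside]
        ht <- tr$apex_height[t]
        deciduous <- tr$species[t] %in% DECIDUOUS
        shape <- if (deciduous) (d / cr)^2 else d / cr
        surf <- ht - shape * (config$crown_depth_frac * ht)
        if (deciduous && config$leaf_off_bias > 0)
          surf <- surf - config$leaf_off_bias
        better <- surf > canopy[cand]
        canopy[cand[better]] <- surf[better]
        hit_deciduous[cand[better]] <- deciduous
      }
    }
    ground_z <- terrain(px, py)
    crowned <- canopy >= 0.05
    noise1 <- if (config$vertical_noise_sd > 0)
      rnorm(np, 0, config$vertical_noise_sd) else numeric(np)
    noise2 <- if (config$vertical_noise_sd > 0)
      rnorm(np, 0, config$vertical_noise_sd) else numeric(np)
    veg_class <- function(hh) ifelse(hh <= 0.4, 3L, ifelse(hh <= 2, 4L, 5L))
    first <- data.table(
      x = px[crowned], y = py[crowned],
      z = ground_z[crowned] + canopy[crowned] + noise1[crowned],
      return_number = 1L, number_of_returns = 2L,
      class_code = veg_class(canopy[crowned]))
    last <- data.table(
      x = px[crowned], y = py[crowned],
      z = ground_z[crowned] + noise2[crowned],
      return_number = 2L, number_of_returns = 2L, class_code = 2L)
    open <- data.table(
      x = px[!crowned], y = py[!crowned],
      z = ground_z[!crowned] + noise1[!crowned],
      return_number = 1L, number_of_returns = 1L, class_code = 2L)
    pts <- rbind(first, last, open)
    if (config$noise_fraction > 0) {
      nn <- max(1L, floor(config$noise_fraction * nrow(pts)))
      nzx <- runif(nn, ext[["xmin"]], ext[["xmax"]])
      nzy <- runif(nn, ext[["ymin"]], ext[["ymax"]])
      pts <- rbind(pts, data.table(
        x = nzx, y = nzy, z = terrain(nzx, nzy) + runif(nn, -10, 40),
        return_number = 1L, number_of_returns = 1L, class_code = 7L))
    }
    point_cloud(pts, crs = "local", epoch = epoch)
  })
}

#' Synthetic field inventory of stand heights
#'
#' Emulates the surveyor's record: per unit, `n_sample` trees of the
#' dominant species are sampled (without replacement; fewer if the unit has
#' fewer), each measured height gets an independent Gaussian error of sd
#' `height_noise_sd`, and the mean of the measurements is rounded to whole
#' meters. A unit with no trees of its dominant species gets a missing
#' height (never 0).
#'
#' @param trees tree table covering the scene.
#' @param units [forest_units()] layer (provides addresses and dominant
#'   species).
#' @param n_sample trees measured per unit (>= 1).
#' @param height_noise_sd per-tree measurement error sd (m).
#' @param seed RNG seed.
#' @return data.table: `forest_address`, `species`, `n_measured`,
#'   `height_raw` (unrounded mean), `height` (whole m, `NA` when no trees).
#' @export
generate_inventory <- function(trees, units, n_sample = 10,
                               height_noise_sd = 0.3, seed = 1L) {
  stopifnot(n_sample >= 1)
  tr <- copy(as.data.table(trees))
  if (!"in_nea" %in% names(tr)) tr[, in_nea := FALSE]
  un <- as.data.table(units)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(un)), function(i) {
      addr <- un$forest_address[i]
      sp <- un$dominant_species[i]
      avail <- tr[unit_id == addr & species == sp & in_nea == FALSE]
      if (!nrow(avail))
        return(data.table(forest_address = addr, species = sp,
                          n_measured = 0L, height_raw = NA_real_,
                          height = NA_integer_))
      k <- min(n_sample, nrow(avail))
      idx <- sample.int(nrow(avail), k)
      meas <- avail$apex_height[idx] +
        if (height_noise_sd > 0) rnorm(k, 0, height_noise_sd) else 0
      data.table(forest_address = addr, species = sp, n_measured = k,
                 height_raw = mean(meas),
                 height = as.integer(round_height(mean(meas))))
    })
    rbindlist(rows)
  })
}

#' Simulate a complete two-epoch study area
#'
#' One call produces everything the pipeline consumes: terrain, a unit
#' grid, tree lists for both epochs (per-unit true growth rates applied),
#' optional NEA clusters of taller residual trees, point clouds, inventory
#' tables and a truth table. NEA-cluster trees are excluded from inventory
#' sampling and truth means, exactly as a surveyor excludes clusters from
#' the stand.
#'
#' @param config a [scene_config()].
#' @param nx,ny unit grid dimensions.
#' @return list with elements `config`, `terrain`, `units` (truth columns
#'   included), `neas`, `trees`, `clouds`, `inventory` (lists keyed by
#'   epoch tag), and `truth` (per unit: true mean height per epoch, true
#'   growth).
#' @export
simulate_study <- function(config = scene_config(), nx = 4, ny = 4) {
  terrain <- generate_terrain(config)
  units <- generate_units(config, nx, ny)
  trees_old <- rbindlist(lapply(seq_len(nrow(units)), function(i)
    generate_stand(units[i], config, seed = config$seed + 10L + i)))
  trees_old[, in_nea := FALSE]

  # NEA clusters: pockets of taller residual trees inside the first units
  neas <- NULL
  if (config$n_neas > 0) {
    n_nea <- min(config$n_neas, nrow(units))
    r_nea <- 6
    nea <- with_seed(config$seed + 400L, {
      rows <- vector("list", n_nea)
      geoms <- vector("list", n_nea)
      for (k in seq_len(n_nea)) {
        g <- units$geometry[[k]]
        bb <- c(range(g[, 1]), range(g[, 2]))
        cx <- runif(1, bb[1] + r_nea + 2, bb[2] - r_nea - 2)
        cy <- runif(1, bb[3] + r_nea + 2, bb[4] - r_nea - 2)
        ang <- seq(0, 2 * pi, length.out = 17)[-17]
        geoms[[k]] <- cbind(cx + r_nea * cos(ang), cy + r_nea * sin(ang))
        m <- rpois(1, 4) + 2L
        rr <- sqrt(runif(m)) * (r_nea - 1)
        aa <- runif(m, 0, 2 * pi)
        hh <- units$true_mean_height[k] + 6 + rnorm(m, 0, 0.5)
        rows[[k]] <- data.table(
          id = seq_len(m) + 100000L,
          x = cx + rr * cos(aa), y = cy + rr * sin(aa),
          apex_height = hh,
          crown_radius = config$crown_slope * hh + config$crown_intercept,
          species = units$dominant_species[k],
          unit_id = units$forest_address[k],
          in_nea = TRUE)
      }
      list(trees = rbindlist(rows), geoms = geoms)
    })
    trees_old <- rbind(trees_old, nea$trees)
    neas <- forest_units(
      data.table(forest_address = sprintf("NEA%02d", seq_len(n_nea)),
                 land_kind = "nea"),
      nea$geoms, crs = "local")
  }

  # per-unit true growth rates; NEA residual trees grow like their unit
  rate_of <- setNames(units$growth_rate, units$forest_address)
  trees_new <- rbindlist(lapply(split(trees_old, trees_old$unit_id),
    function(tt) grow_stand(tt, config$years, rate_of[[tt$unit_id[1]]],
                            jitter_sd = config$growth_jitter_sd,
                            seed = config$seed + 500L +
                              match(tt$unit_id[1], units$forest_address),
                            config = config)))

  clouds <- list(
    simulate_point_cloud(trees_old, terrain, config, config$epochs[1],
                         seed = config$seed + 1000L),
    simulate_point_cloud(trees_new, terrain, config, config$epochs[2],
                         seed = config$seed + 1001L))
  names(clouds) <- config$epochs

  inventory <- list(
    generate_inventory(trees_old, units, config$n_sample,
                       config$inventory_noise_sd, seed = config$seed + 2000L),
    generate_inventory(trees_new, units, config$n_sample,
                       config$inventory_noise_sd, seed = config$seed + 2001L))
  names(inventory) <- config$epochs

  truth_mean <- function(tt) {
    tt <- tt[in_nea == FALSE]
    m <- merge(data.table(forest_address = units$forest_address,
                          dominant_species = units$dominant_species),
               tt[, .(unit_id, species, apex_height)],
               by.x = "forest_address", by.y = "unit_id")
    m <- m[species == dominant_species]
    m[, .(true_mean = mean(apex_height)), by = forest_address]
  }
  t1 <- truth_mean(trees_old)
  t2 <- truth_mean(trees_new)
  truth <- merge(t1, t2, by = "forest_address", suffixes = c("_old", "_new"))
  truth[, true_growth := true_mean_new - true_mean_old]
  truth <- merge(truth,
                 as.data.table(units)[, .(forest_address, growth_rate)],
                 by = "forest_address")

  trees <- list(trees_old, trees_new)
  names(trees) <- config$epochs
  list(config = config, terrain = terrain, units = units, neas = neas,
       trees = trees, clouds = clouds, inventory = inventory, truth = truth)
}
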
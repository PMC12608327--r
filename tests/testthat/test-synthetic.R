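test_that("terrain generator honors amplitude, determinism and flat case", {
  cfg <- small_config()
  flat <- generate_terrain(cfg)
  expect_equal(flat(c(0, 25, 50), c(3, 7, 50)), c(0, 0, 0))

  cfg2 <- small_config(relief_amplitude = 5, relief_length = 20)
  ter <- generate_terrain(cfg2)
  ter_again <- generate_terrain(cfg2)
  px <- runif(100, 0, 50); py <- runif(100, 0, 50)
  expect_identical(ter(px, py), ter_again(px, py))

  gx <- seq(0, 50, by = 0.25)
  grid_vals <- as.vector(outer(gx, gx, function(a, b) ter(a, b)))
  expect_lte(max(grid_vals) - mean(grid_vals), 2 * 5 + 1e-9)
  expect_lte(max(abs(grid_vals - mean(grid_vals))), 2 * 5)
  # on the normalization reference grid the field is exactly centered in
  # [-A, A]
  rx <- seq(0, 50, length.out = 201)
  ref <- as.vector(outer(rx, rx, function(a, b) ter(a, b)))
  expect_lt(abs(mean(ref)), 1e-9)
  expect_equal(max(abs(ref)), 5, tolerance = 1e-9)
})

test_that("terrain rejects an empty extent", {
  expect_error(scene_config(extent = c(xmin = 0, xmax = 0,
                                       ymin = 0, ymax = 10)),
               "extent")
})

test_that("stand generation: Poisson counts, purity, degenerate inputs", {
  cfg <- small_config(stem_density = 400, minority_fraction = 0)
  unit <- one_unit()   # 1 ha
  s1 <- generate_stand(unit, cfg, seed = 123)
  s2 <- generate_stand(unit, cfg, seed = 123)
  expect_identical(s1, s2)
  expect_true(all(s1$species == "pine"))
  expect_true(all(point_in_polygon(s1$x, s1$y, unit$geometry[[1]])))
  expect_true(all(s1$apex_height > 0) && all(s1$crown_radius > 0))

  # Poisson(400) sampling: mean over replicates close to 400, variance too
  counts <- vapply(1:40, function(k)
    nrow(generate_stand(unit, cfg, seed = 1000 + k)), 0)
  expect_gt(mean(counts), 400 - 3 * sqrt(400 / 40))
  expect_lt(mean(counts), 400 + 3 * sqrt(400 / 40))

  expect_equal(nrow(generate_stand(unit, small_config(stem_density = 0),
                                   seed = 1)), 0)
  degen <- one_unit(ring = cbind(c(0, 10, 20), c(0, 0, 0)))
  expect_warning(out <- generate_stand(degen, cfg, seed = 1), "degenerate")
  expect_equal(nrow(out), 0)
})

test_that("grow_stand applies linear growth with clamping", {
  cfg <- small_config()
  trees <- generate_stand(one_unit(), cfg, seed = 5)
  same <- grow_stand(trees, 0, 0.25, config = cfg)
  expect_equal(same$apex_height, trees$apex_height)

  grown <- grow_stand(trees, 9, 0.222, config = cfg)
  expect_equal(grown$apex_height, trees$apex_height + 9 * 0.222)
  expect_equal(grown$x, trees$x)

  dieback <- grow_stand(trees, 9, -5, config = cfg)
  expect_true(all(dieback$apex_height >= 0))
  expect_true(any(dieback$apex_height == 0))

  expect_error(grow_stand(trees, -1, 0.2, config = cfg), "years")
})

test_that("open-ground cloud matches density and noise moments", {
  cfg <- small_config(vertical_noise_sd = 0.2)
  terrain <- generate_terrain(cfg)
  empty <- data.table(id = integer(), x = numeric(), y = numeric(),
                      apex_height = numeric(), crown_radius = numeric(),
                      species = character(), unit_id = character())
  cl <- simulate_point_cloud(empty, terrain, cfg, seed = 42)
  expect_true(all(cl$class_code == 2L))
  ratio <- nrow(cl) / (2500 * cfg$pulse_density)
  expect_gte(ratio, 0.95); expect_lte(ratio, 1.05)
  expect_lt(abs(mean(cl$z)), 3 * 0.2 / sqrt(nrow(cl)))
  expect_equal(sd(cl$z), 0.2, tolerance = 0.05)
  # determinism: byte-identical with the same seed
  expect_identical(as.data.table(cl),
                   as.data.table(simulate_point_cloud(empty, terrain, cfg,
                                                      seed = 42)))
})

test_that("single cone crown reproduces its apex height geometrically", {
  cfg <- small_config(vertical_noise_sd = 0)
  terrain <- generate_terrain(cfg)
  tree <- data.table(id = 1L, x = 25, y = 25, apex_height = 20,
                     crown_radius = 3, species = "pine", unit_id = "U001")
  cl <- simulate_point_cloud(tree, terrain, cfg, seed = 9)
  first <- cl[cl$return_number == 1L & cl$class_code %in% c(3L, 4L, 5L), ]
  ground <- cl[cl$class_code == 2L, ]
  expect_gt(nrow(first), 10)
  # highest first return within one pulse-grid jitter of the 20 m apex:
  # the cone drops crown_depth/crown_radius = 3 m per meter off-apex, and
  # the nearest jittered pulse is at most s*sqrt(2) away
  s <- 1 / sqrt(cfg$pulse_density)
  expect_lte(max(first$z), 20)
  expect_gte(max(first$z), 20 - 3 * s * sqrt(2))
  expect_equal(mean(ground$z), 0, tolerance = 1e-9)
})

test_that("vegetation classes follow the height bands", {
  cfg <- small_config(vertical_noise_sd = 0)
  terrain <- generate_terrain(cfg)
  mk <- function(h) data.table(id = 1L, x = 25, y = 25, apex_height = h,
                               crown_radius = 4, species = "pine",
                               unit_id = "U001")
  # a 1.5 m surface return is medium vegetation (0.40-2.00 m): class 4
  cl <- simulate_point_cloud(mk(1.5), terrain, cfg, seed = 3)
  apex_cls <- cl$class_code[which.max(cl$z)]
  expect_equal(apex_cls, 4L)
  cl3 <- simulate_point_cloud(mk(0.3), terrain, cfg, seed = 3)
  expect_equal(cl3$class_code[which.max(cl3$z)], 3L)
  cl5 <- simulate_point_cloud(mk(12), terrain, cfg, seed = 3)
  expect_equal(cl5$class_code[which.max(cl5$z)], 5L)
})

test_that("synthetic inventory means, missing units and sampling spread", {
  cfg <- small_config()
  unit <- one_unit()
  trees <- data.table(id = 1:40, x = runif(40, 1, 49), y = runif(40, 1, 49),
                      apex_height = 18, crown_radius = 2.3,
                      species = "pine", unit_id = "U001")
  inv <- generate_inventory(trees, unit, n_sample = 10,
                            height_noise_sd = 0, seed = 1)
  expect_equal(inv$height, 18L)

  no_trees <- trees[0]
  inv0 <- generate_inventory(no_trees, unit, n_sample = 10,
                             height_noise_sd = 0.3, seed = 1)
  expect_true(is.na(inv0$height))
  expect_false(identical(inv0$height, 0L))

  # Monte Carlo vs closed form: sd of the unrounded unit mean over many
  # seeds is sigma / sqrt(n_sample) when all trees are identical
  raws <- vapply(1:400, function(s)
    generate_inventory(trees, unit, n_sample = 10, height_noise_sd = 0.3,
                       seed = s)$height_raw, 0)
  expect_equal(sd(raws), 0.3 / sqrt(10), tolerance = 0.1)
})

test_that("simulate_study is reproducible and records ground truth", {
  cfg <- small_config(n_neas = 1)
  st1 <- simulate_study(cfg, nx = 1, ny = 2)
  st2 <- simulate_study(cfg, nx = 1, ny = 2)
  expect_identical(as.data.table(st1$clouds[[1]]),
                   as.data.table(st2$clouds[[1]]))
  expect_identical(st1$inventory, st2$inventory)
  expect_identical(st1$truth, st2$truth)
  expect_equal(nrow(st1$truth), 2)
  expect_true(all(c("true_mean_old", "true_mean_new", "true_growth")
                  %in% names(st1$truth)))
  # growth truth within the configured rate window
  expect_true(all(st1$truth$true_growth / cfg$years >
                    cfg$growth_rate_range[1] - 0.2))
  expect_true(all(st1$truth$true_growth / cfg$years <
                    cfg$growth_rate_range[2] + 0.2))
})
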
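test_that("pearson: limits, weighting identity, failure modes", {
  x <- c(1, 2, 5, 7, 9)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -x), -1)
  expect_error(pearson(x, rep(3, 5)), "zero variance")
  expect_error(pearson(1, 2), "at least two")

  # weighted form equals brute-force pair expansion
  tab <- zbrzyca_table("increments")
  r_w <- pearson(tab$lidar_increment, tab$inventory_increment, tab$n)
  xe <- rep(tab$lidar_increment, tab$n)
  ye <- rep(tab$inventory_increment, tab$n)
  expect_equal(r_w, cor(xe, ye), tolerance = 1e-12)
})

test_that("agreement statistics and their decomposition", {
  x <- c(2, 3); y <- c(1, 2)
  s <- agreement_stats(x, y)
  expect_equal(s$bias, 1)
  expect_equal(s$rmse, 1)
  expect_equal(s$rbias, 100 * 2 / 3, tolerance = 1e-9)

  perf <- agreement_stats(1:5, 1:5)
  expect_equal(perf$bias, 0); expect_equal(perf$rmse, 0)
  expect_equal(perf$r2_identity, 1); expect_equal(perf$rbias, 0)

  off <- agreement_stats(2:6, 1:5)
  expect_equal(off$bias, 1); expect_equal(off$rmse, 1)

  # rmse^2 == bias^2 + population variance of the differences
  set.seed(3)
  for (k in 1:5) {
    a <- rnorm(50); b <- rnorm(50)
    st <- agreement_stats(a, b)
    d <- a - b
    expect_equal(st$rmse^2, st$bias^2 + mean((d - mean(d))^2),
                 tolerance = 1e-12)
    expect_gte(st$rmse, abs(st$bias))
  }

  zero <- agreement_stats(c(1, -1, 2), c(1, -1.5, 0.5))
  expect_true(is.na(agreement_stats(c(1, 2), c(-1, 1))$rbias))
})

test_that("class tabulation reproduces the published site-type aggregates", {
  t2 <- zbrzyca_table("site_2013")
  wide <- class_tabulate(t2, class_col = "diff_class",
                         group_col = "site_type", measure = "area")
  tot <- wide[wide$site_type == "TOTAL", ]
  expect_equal(tot[["-2"]], 115.8)
  expect_equal(tot[["0"]], 335.77)
  neg <- sum(unlist(tot[, c("-5", "-4", "-3", "-2")]))
  pos <- sum(unlist(tot[, c("2", "3", "4", "5", "6")]))
  expect_equal(neg, 142.11)
  expect_equal(pos, 95.72)
  # empty input
  expect_equal(nrow(class_tabulate(t2[0], group_col = "site_type",
                                   measure = "area")), 1)
})

test_that("increment cross-tabulation counts pairs", {
  pairs <- data.table(inventory_increment = c(1, 1, 2),
                      lidar_increment = c(2, 2, 0))
  ct <- crosstab_increments(pairs)
  expect_equal(ct[ct$inventory_increment == 1 & ct$lidar_increment == 2, ]$n,
               2)
  expect_equal(sum(ct$n), 3)
  single <- crosstab_increments(data.table(inventory_increment = 1,
                                           lidar_increment = 2))
  expect_equal(single$n, 1)
})

test_that("Jenks breaks minimize within-class variance", {
  b <- jenks_breaks(c(1, 2, 3, 100, 101, 102), 2)
  expect_gt(b[2], 3); expect_lt(b[2], 100)

  v <- c(4, 9, 1, 7)
  b2 <- jenks_breaks(v, 4)
  expect_equal(attr(b2, "within_ss"), 0)

  # randomized oracle: no random partition beats the DP optimum
  set.seed(42)
  vals <- sort(runif(50, 0, 100))
  opt <- attr(jenks_breaks(vals, 4), "within_ss")
  ssd <- function(x) sum((x - mean(x))^2)
  worst <- min(vapply(1:1000, function(i) {
    cuts <- sort(sample(1:49, 3))
    grp <- findInterval(1:50, c(cuts + 0.5))
    sum(tapply(vals, grp, ssd))
  }, 0))
  expect_lte(opt, worst + 1e-9)

  # order invariance and k validation
  expect_equal(jenks_breaks(rev(vals), 4), jenks_breaks(vals, 4))
  expect_error(jenks_breaks(c(1, 1, 2), 3), "distinct")
})

test_that("detection metrics reproduce hand confusion matrices", {
  ref <- data.table(x = as.numeric(1:10), y = rep(0, 10))
  exact <- detection_metrics(ref, ref, match_radius = 0.5)
  expect_equal(exact$precision, 1)
  expect_equal(exact$recall, 1)
  expect_equal(exact$f1, 1)
  expect_equal(exact$count_rmse, 0)

  # 8 of 10 matched + 2 false detections: P = R = F1 = 0.8
  det <- rbind(ref[1:8], data.table(x = c(50, 60), y = c(0, 0)))
  m <- detection_metrics(det, ref, match_radius = 0.5)
  expect_equal(c(m$tp, m$fp, m$fn), c(8, 2, 2))
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 0.8)

  none <- detection_metrics(ref[0], ref, match_radius = 0.5)
  expect_equal(none$precision, 0)
  expect_equal(none$recall, 0)
  expect_error(detection_metrics(ref, ref[0]), "empty reference")
})

test_that("greedy matching is one-to-one within the radius", {
  ref <- data.table(x = c(0, 1), y = c(0, 0))
  det <- data.table(x = 0.4, y = 0)   # near both, may match only one
  m <- detection_metrics(det, ref, match_radius = 2)
  expect_equal(m$tp, 1)
  expect_equal(m$fn, 1)
})

test_that("Monte Carlo stand-height uncertainty matches sigma/sqrt(n)", {
  # sd of the SE estimator is sigma/sqrt(2*n_reps) ~ 0.005; allow ~3 sd
  one <- mc_height_uncertainty(sigma = 0.3, n_trees = 1, n_reps = 2000,
                               seed = 1)
  expect_equal(one$se_mc, 0.3, tolerance = 0.05)

  a <- mc_height_uncertainty(sigma = 0.3, n_trees = 25, n_reps = 4000,
                             seed = 2)
  b <- mc_height_uncertainty(sigma = 0.3, n_trees = 100, n_reps = 4000,
                             seed = 3)
  expect_equal(a$se_mc / b$se_mc, 2, tolerance = 0.1)

  # convergence to the closed form within 2% at large n_reps
  big <- mc_height_uncertainty(sigma = 0.3, n_trees = 4, n_reps = 1e5,
                               seed = 4)
  expect_equal(big$se_mc, big$se_analytic, tolerance = 0.02)
  # determinism
  expect_identical(mc_height_uncertainty(seed = 9)$se_mc,
                   mc_height_uncertainty(seed = 9)$se_mc)
})
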
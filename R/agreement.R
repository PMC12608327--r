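#' Weighted Pearson product-moment correlation
#'
#' Pearson's r with optional non-negative case weights, used to correlate
#' LiDAR and inventory height increments directly from a cross-tabulation
#' (weights = cell counts) without expanding it to unit-level rows. With
#' integer weights the result is identical (to machine precision) to
#' expanding each pair `(x_i, y_i)` `w_i` times and computing unweighted r.
#'
#' @param x,y numeric vectors of equal length.
#' @param w optional weights (pair multiplicities); default all 1.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(x, y, w = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (is.null(w)) w <- rep(1, length(x))
  keep <- !is.na(x) & !is.na(y) & !is.na(w) & w > 0
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  if (sum(w) < 2) stop("need at least two (weighted) observations")
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xb)^2)
  syy <- sum(w * (y - yb)^2)
  if (sxx == 0 || syy == 0)
    stop("correlation undefined: zero variance in x or y")
  sum(w * (x - xb) * (y - yb)) / sqrt(sxx * syy)
}

#' Agreement statistics between two increment series
#'
#' Summarizes how LiDAR-derived increments `x` agree with inventory
#' increments `y`: `bias = mean(x - y)`, `rmse = sqrt(mean((x - y)^2))`,
#' `rbias = 100 * bias / mean(y)` (percent of the mean reference increment;
#' `NA` when `mean(y)` is 0), and two R-squared variants, because the
#' conventional definitions diverge here: `r2_pearson` is the squared
#' correlation (agreement up to a linear recalibration) and `r2_identity`
#' is `1 - SS_res/SS_tot` about the identity line `x = y` (agreement with
#' the reference as-is, can be negative).
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return list with `n`, `r`, `bias`, `rmse`, `r2_pearson`, `r2_identity`,
#'   `rbias`.
#' @export
agreement_stats <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2) stop("need at least two complete pairs")
  d <- x - y
  bias <- mean(d)
  rmse <- sqrt(mean(d^2))
  r <- if (var(x) > 0 && var(y) > 0) pearson(x, y) else NA_real_
  sst <- sum((y - mean(y))^2)
  r2_identity <- if (sst > 0) 1 - sum(d^2) / sst else NA_real_
  rbias <- if (mean(y) != 0) 100 * bias / mean(y) else NA_real_
  list(n = n, r = r, bias = bias, rmse = rmse,
       r2_pearson = if (is.na(r)) NA_real_ else r^2,
       r2_identity = r2_identity, rbias = rbias)
}

#' Tabulate units by group and height-difference class
#'
#' Builds the class-by-group table used to audit height agreement: rows are
#' the levels of `group` (site type or dominant species), columns the
#' height-difference classes of [diff_class_levels()], cells either unit
#' counts or summed areas (ha, 2 decimals), plus a `TOTAL` row.
#'
#' @param data data.frame with one row per unit.
#' @param class_col name of the class column (values among
#'   [diff_class_levels()]).
#' @param group_col name of the grouping column.
#' @param measure `"count"` or `"area"`.
#' @param area_col name of the area column (ha) when `measure = "area"`.
#' @return data.table, one row per group plus `TOTAL`, one column per class
#'   present plus the group column.
#' @export
class_tabulate <- function(data, class_col = "diff_class",
                           group_col = "site_type",
                           measure = c("count", "area"),
                           area_col = "area_ha") {
  measure <- match.arg(measure)
  dt <- as.data.table(data)
  lv <- diff_class_levels()
  lv <- lv[lv %in% unique(dt[[class_col]])]
  if (!nrow(dt)) {
    out <- data.table(group = "TOTAL")
    setnames(out, "group", group_col)
    return(out[])
  }
  val <- if (measure == "count") rep(1, nrow(dt)) else dt[[area_col]]
  agg <- dt[, .(v = if (measure == "count") .N else sum(get(area_col))),
            by = c(group_col, class_col)]
  wide <- dcast(agg, paste0(group_col, " ~ ", class_col), value.var = "v",
                fill = 0)
  ord <- c(group_col, lv[lv %in% names(wide)])
  wide <- wide[, ord, with = FALSE]
  tot <- wide[, lapply(.SD, sum), .SDcols = setdiff(names(wide), group_col)]
  tot[, (group_col) := "TOTAL"]
  out <- rbind(wide, tot, use.names = TRUE, fill = TRUE)
  num <- setdiff(names(out), group_col)
  if (measure == "area")
    out[, (num) := lapply(.SD, function(v) round(v, 2)), .SDcols = num]
  out[]
}

#' Cross-tabulation of inventory vs LiDAR increments
#'
#' @param pairs data.frame with columns `inventory_increment` and
#'   `lidar_increment` (whole meters).
#' @return data.table of counts with one row per occupied
#'   (inventory, LiDAR) cell, plus the full matrix as
#'   `attr(out, "matrix")` (rows = inventory increment, cols = LiDAR).
#' @export
crosstab_increments <- function(pairs) {
  p <- as.data.table(pairs)
  out <- p[, .(n = .N), by = .(inventory_increment, lidar_increment)]
  setorder(out, inventory_increment, lidar_increment)
  tab <- table(factor(p$inventory_increment),
               factor(p$lidar_increment))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  setattr(out, "matrix", m)
  out[]
}

#' Jenks natural breaks (exact Fisher optimal partition)
#'
#' Splits a numeric vector into `k` classes minimizing the total
#' within-class sum of squared deviations, by dynamic programming over the
#' sorted values (Fisher's algorithm, O(k n^2)). The result is the global
#' optimum, deterministic, and invariant to input order. Used to map
#' within-unit site-potential variability from tree-top heights.
#'
#' @param values numeric vector (>= k distinct values).
#' @param k number of classes (>= 2).
#' @return numeric vector of `k + 1` break points: `min(values)`, the `k-1`
#'   interior breaks (upper edge of each lower class, taken as the midpoint
#'   between adjacent class-boundary values), `max(values)`. Class
#'   membership: value in class `c` iff `breaks[c] <= value <= breaks[c+1]`
#'   (lower-open except the first).
#' @export
jenks_breaks <- function(values, k) {
  v <- sort(values[!is.na(values)])
  n <- length(v)
  if (k < 2) stop("k must be >= 2")
  if (length(unique(v)) < k)
    stop("k exceeds the number of distinct values")
  # prefix sums for O(1) segment SSD
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  ssd <- function(i, j) {   # segment v[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, k, n)
  split <- matrix(0L, k, n)
  for (j in 1:n) cost[1, j] <- ssd(1, j)
  for (c in 2:k) {
    for (j in c:n) {
      for (m in (c - 1):(j - 1)) {
        val <- cost[c - 1, m] + ssd(m + 1, j)
        if (val < cost[c, j]) {
          cost[c, j] <- val
          split[c, j] <- m
        }
      }
    }
  }
  edges <- integer(k - 1)
  j <- n
  for (c in k:2) {
    edges[c - 1] <- split[c, j]
    j <- split[c, j]
  }
  inner <- (v[edges] + v[edges + 1]) / 2
  breaks <- c(v[1], inner, v[n])
  attr(breaks, "within_ss") <- cost[k, n]
  breaks
}

#' Tree-top detection quality against reference tops
#'
#' Greedy one-to-one matching: all detected-reference pairs within
#' `match_radius` are sorted by distance and consumed nearest-first, each
#' top and each reference point matching at most once. Matched pairs are
#' true positives; unmatched detections false positives; unmatched
#' reference points false negatives. With no detections, precision is
#' reported as 0 by convention (the 0/0 case) and recall as 0.
#'
#' @param detected data.frame with columns `x`, `y` (detected tops).
#' @param reference data.frame with columns `x`, `y` (digitized reference
#'   tops); must be non-empty.
#' @param match_radius maximum matching distance in m.
#' @param plot_id optional vector of plot identifiers for the reference and
#'   detected sets (same plot labels in both); per-plot counts feed
#'   `count_rmse`. Default: one single plot.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `count_rmse`.
#' @export
detection_metrics <- function(detected, reference, match_radius = 2,
                              plot_id = NULL) {
  det <- as.data.table(detected)
  ref <- as.data.table(reference)
  if (!nrow(ref)) stop("empty reference set: metrics undefined")
  if (is.null(plot_id)) {
    det[, plot := 1L]; ref[, plot := 1L]
  } else {
    det[, plot := plot_id$detected]; ref[, plot := plot_id$reference]
  }
  tp <- 0L
  used_det <- rep(FALSE, nrow(det))
  used_ref <- rep(FALSE, nrow(ref))
  if (nrow(det)) {
    cand <- CJ(d = seq_len(nrow(det)), r = seq_len(nrow(ref)))
    cand[, dist := sqrt((det$x[d] - ref$x[r])^2 + (det$y[d] - ref$y[r])^2)]
    cand <- cand[dist <= match_radius][order(dist)]
    for (i in seq_len(nrow(cand))) {
      d <- cand$d[i]; r <- cand$r[i]
      if (!used_det[d] && !used_ref[r]) {
        used_det[d] <- TRUE
        used_ref[r] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  fp <- sum(!used_det)
  fn <- sum(!used_ref)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  plots <- unique(ref$plot)
  nd <- vapply(plots, function(p) sum(det$plot == p), 0)
  nr <- vapply(plots, function(p) sum(ref$plot == p), 0)
  list(tp = tp, fp = fp, fn = fn,
       precision = precision, recall = recall, f1 = f1,
       count_rmse = sqrt(mean((nd - nr)^2)))
}

#' Monte Carlo uncertainty of a stand's mean height
#'
#' Propagates the per-tree height measurement error sigma to the stand mean
#' by simulation: `n_reps` replicate stands of `n_trees` heights with
#' independent Gaussian errors are drawn, and the standard deviation of the
#' replicate means is returned. For large `n_reps` this converges to the
#' closed form `SE = sigma / sqrt(n_trees)`; with the typical ~1000 trees
#' per stand and sigma = 0.3 m the stand-mean uncertainty is below 0.01 m,
#' i.e. negligible against whole-meter height records.
#'
#' @param sigma per-tree height error sd in m (> 0).
#' @param n_trees trees per stand (>= 1).
#' @param n_reps Monte Carlo replicates (>= 100).
#' @param seed RNG seed.
#' @param mean_height true stand mean (shifts nothing; kept for realism of
#'   the simulated heights).
#' @return list with `se_mc` (simulated SE), `se_analytic`
#'   (`sigma/sqrt(n_trees)`) and `n_reps`.
#' @export
mc_height_uncertainty <- function(sigma = 0.3, n_trees = 1000,
                                  n_reps = 1000, seed = NULL,
                                  mean_height = 20) {
  stopifnot(sigma > 0, n_trees >= 1, n_reps >= 100)
  means <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i)
      mean(mean_height + rnorm(n_trees, 0, sigma)), 0)
  })
  list(se_mc = sd(means),
       se_analytic = sigma / sqrt(n_trees),
       n_reps = n_reps)
}
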
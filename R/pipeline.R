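#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end run. The defaults are the
#' reference parameterization of the method: 0.5 m raster resolution, 7 m
#' canopy mask, search-window function `0.16 h + 0.8`, 2 m NEA buffer and
#' drop classes \{0, 7, 8, 12\}.
#'
#' @param resolution raster cell size in m (0.5 default, 1.0 supported).
#' @param mask_threshold CHM mask threshold in m.
#' @param window_slope,window_intercept coefficients of [window_radius()].
#' @param nea_buffer NEA dilation width in m.
#' @param drop_classes point classes rejected before surface modelling.
#' @param rounding height rounding mode, see [round_height()].
#' @param min_inventory_height inventory exclusion threshold in m (stands
#'   at or below it are rejected).
#' @param seed seed forwarded to stochastic stages.
#' @param out_dir optional directory; when set, per-stage artifacts (ASCII
#'   rasters, GeoJSON tops, CSV tables) are written there.
#' @return a `run_config` list.
#' @export
run_config <- function(resolution = 0.5, mask_threshold = 7,
                       window_slope = 0.16, window_intercept = 0.8,
                       nea_buffer = 2, drop_classes = c(0L, 7L, 8L, 12L),
                       rounding = "half_up", min_inventory_height = 6,
                       seed = 1L, out_dir = NULL) {
  stopifnot(resolution > 0, mask_threshold > 0)
  structure(list(resolution = resolution, mask_threshold = mask_threshold,
                 window_slope = window_slope,
                 window_intercept = window_intercept,
                 nea_buffer = nea_buffer,
                 drop_classes = as.integer(drop_classes),
                 rounding = rounding,
                 min_inventory_height = min_inventory_height,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

process_epoch <- function(cloud, units, neas, config) {
  filtered <- filter_classes(cloud, config$drop_classes)
  grid <- grid_for_bbox(cloud_bbox(filtered), res = config$resolution,
                        crs = attr(filtered, "crs"))
  dsm <- make_dsm(filtered, grid = grid)
  dtm <- make_dtm(filtered, grid = grid)
  chm <- compute_chm(dsm, dtm)
  chm_s <- gaussian_smooth(chm)
  chm_m <- mask_below(chm_s, config$mask_threshold)
  tops <- detect_treetops(chm_m, config$window_slope,
                          config$window_intercept)
  tops_f <- filter_treetops(tops, units, neas, config$nea_buffer)
  heights <- stand_heights(tops_f, config$rounding)
  list(filtered = filtered, dsm = dsm, dtm = dtm, chm = chm_m,
       tops = tops, tops_filtered = tops_f, heights = heights,
       counts = c(returns_in = nrow(cloud), returns_kept = nrow(filtered),
                  tops_detected = nrow(tops), tops_kept = nrow(tops_f),
                  units_with_height = nrow(heights)))
}

#' Run the full two-epoch pipeline
#'
#' Executes, for each epoch: class filtering, TIN DSM/DTM on a shared
#' snapped grid, CHM differencing, smoothing, masking, tree-top detection
#' and unit/NEA filtering, and occurrence-weighted stand heights. Then
#' matches units across epochs spatially, filters non-comparable pairs,
#' forms increment pairs (excluding gross-error units) and computes
#' agreement statistics and the increment cross-tabulation.
#'
#' The report keeps a complete filter bookkeeping (units and tops surviving
#' every stage): unit-selection rules in forest documentation workflows are
#' not always reproducible from attributes alone, so transparency about
#' what was dropped where substitutes for any hidden rule.
#'
#' @param study a study list as produced by [simulate_study()]: elements
#'   `clouds` (two [point_cloud()]s), `units` (a [forest_units()] layer or
#'   a two-element list of per-epoch layers), `neas` (optional),
#'   `inventory` (two inventory tables with `forest_address`, `height`),
#'   and optionally `config` (its `years` feed the age attributes).
#' @param config a [run_config()].
#' @return list with per-epoch results, `matches`, `pairs`, `stats`,
#'   `crosstab` and a `counts` bookkeeping vector.
#' @export
run_pipeline <- function(study, config = run_config()) {
  epochs <- names(study$clouds)
  stopifnot(length(epochs) == 2)
  units_by_epoch <- if (inherits(study$units, "forest_units"))
    list(study$units, study$units) else study$units
  years <- study$config$years %||% NA_real_

  attach_inventory <- function(units, inv, epoch, age_offset = 0) {
    u <- as.data.table(units)
    for (col in c("inventory_height", "epoch"))
      if (col %in% names(u)) u[, (col) := NULL]
    inv <- as.data.table(inv)[, .(forest_address,
                                  inventory_height = as.numeric(height))]
    u <- merge(u, inv, by = "forest_address", all.x = TRUE)
    if ("age" %in% names(u)) u[, age := age + age_offset]
    u[, epoch := epoch]
    res <- forest_units(u[, !"geometry"], u$geometry,
                        crs = attr(units, "crs"))
    res
  }
  units_old <- attach_inventory(units_by_epoch[[1]],
                                study$inventory[[1]], epochs[1])
  units_new <- attach_inventory(units_by_epoch[[2]], study$inventory[[2]],
                                epochs[2],
                                age_offset = if (is.na(years)) 0 else years)

  res_old <- process_epoch(study$clouds[[1]], units_old, study$neas, config)
  res_new <- process_epoch(study$clouds[[2]], units_new, study$neas, config)

  matches <- match_units(units_old, units_new)
  kept <- filter_matched(matches)
  pairs <- increment_pairs(kept, res_old$heights, res_new$heights)

  stats <- if (nrow(pairs) >= 2)
    agreement_stats(pairs$lidar_increment, pairs$inventory_increment)
  else NULL
  ctab <- if (nrow(pairs)) crosstab_increments(pairs) else NULL

  counts <- c(setNames(res_old$counts, paste0(epochs[1], "_",
                                              names(res_old$counts))),
              setNames(res_new$counts, paste0(epochs[2], "_",
                                              names(res_new$counts))),
              units_old = nrow(units_old), units_new = nrow(units_new),
              matched = nrow(matches), after_age_filter = nrow(kept),
              analysed_pairs = nrow(pairs))

  out <- list(epochs = setNames(list(res_old, res_new), epochs),
              units = list(old = units_old, new = units_new),
              matches = matches, pairs = pairs, stats = stats,
              crosstab = ctab, counts = counts, config = config)
  if (!is.null(config$out_dir)) write_run_outputs(out, config$out_dir)
  out
}

write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ep in names(run$epochs)) {
    r <- run$epochs[[ep]]
    write_asc(r$chm, file.path(dir, paste0("chm_", ep, ".asc")))
    fwrite(r$tops_filtered[, .(id, x, y, height, radius, forest_address)],
           file.path(dir, paste0("tops_", ep, ".csv")))
    fwrite(r$heights, file.path(dir, paste0("stand_heights_", ep, ".csv")))
  }
  if (nrow(run$pairs))
    fwrite(run$pairs, file.path(dir, "increment_pairs.csv"))
  report <- list(counts = as.list(run$counts), stats = run$stats)
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "report.json"))
  invisible(dir)
}

#' Command-line entry point
#'
#' A minimal CLI around the pipeline:
#' \preformatted{
#'   Rscript -e 'standgrowth::standgrowth_cli()' simulate --seed 7 --out scene/
#'   Rscript -e 'standgrowth::standgrowth_cli()' all --seed 7 --out results/
#' }
#' `simulate` writes the synthetic scene (clouds as the text point dialect,
#' layers as GeoJSON, inventories as CSV); `all` simulates and runs the
#' full pipeline, writing per-stage artifacts and `report.json`.
#'
#' @param args character vector of CLI arguments (default: the command
#'   line).
#' @return invisibly, the run report (`all`) or the scene directory
#'   (`simulate`).
#' @export
standgrowth_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: (simulate|all) [--seed N] [--out DIR] [--res R] [--nx N] [--ny N]"
  if (!length(args)) stop(usage, call. = FALSE)
  cmd <- args[1]
  opt <- list(seed = 1L, out = "standgrowth_out", res = 0.5, nx = 4L, ny = 4L)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt)) stop("unknown option --", key, "\n", usage)
    val <- args[i + 1]
    opt[[key]] <- if (is.integer(opt[[key]])) as.integer(val)
                  else if (is.numeric(opt[[key]])) as.numeric(val)
                  else val
    i <- i + 2
  }
  cfg <- scene_config(seed = opt$seed)
  study <- simulate_study(cfg, nx = opt$nx, ny = opt$ny)
  if (cmd == "simulate") {
    dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
    for (ep in names(study$clouds))
      write_cloud(study$clouds[[ep]],
                  file.path(opt$out, paste0("cloud_", ep, ".xyz")))
    write_units_geojson(study$units, file.path(opt$out, "units.geojson"))
    if (!is.null(study$neas))
      write_units_geojson(study$neas, file.path(opt$out, "neas.geojson"))
    for (ep in names(study$inventory))
      fwrite(study$inventory[[ep]],
             file.path(opt$out, paste0("inventory_", ep, ".csv")))
    fwrite(study$truth, file.path(opt$out, "truth.csv"))
    message("scene written to ", opt$out)
    return(invisible(opt$out))
  }
  if (cmd == "all") {
    run <- run_pipeline(study, run_config(resolution = opt$res,
                                          seed = opt$seed,
                                          out_dir = opt$out))
    message("pipeline finished; report in ",
            file.path(opt$out, "report.json"))
    return(invisible(run))
  }
  stop("unknown command '", cmd, "'\n", usage, call. = FALSE)
}
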
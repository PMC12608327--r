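#' Height-dependent search radius for tree-top detection
#'
#' The local-maximum search window grows linearly with canopy height,
#' `f(h) = slope * h + intercept` meters, reflecting the near-linear
#' relation between crown diameter and tree height in the pine-dominated
#' stands the method targets. Defaults: slope 0.16, intercept 0.8 m (so a
#' 20 m tree is searched within a 4 m radius).
#'
#' @param height canopy height(s) in m (>= 0).
#' @param slope,intercept window-function coefficients.
#' @return search radius in m.
#' @export
window_radius <- function(height, slope = 0.16, intercept = 0.8) {
  if (any(height < 0, na.rm = TRUE)) stop("height must be non-negative")
  slope * height + intercept
}

#' Detect tree tops on a smoothed, masked canopy height model
#'
#' A cell is reported as a tree top when its value is greater than or equal
#' to every non-NA cell whose center lies within the circular window of
#' radius [window_radius()] of its own (post-smoothing) height. Exact height
#' ties inside a window are broken deterministically: the cell with the
#' smallest (row, col) index wins, so a flat plateau yields exactly one top.
#' Each top is returned with its CHM height and the radius actually used.
#'
#' Feed this the smoothed and masked CHM: masking at 7 m guarantees the
#' window radius is at least ~1.9 m, i.e. always wider than one cell at the
#' supported resolutions, which the tie-break relies on.
#'
#' @param chm a [raster_grid()] (smoothed, masked CHM).
#' @param slope,intercept coefficients of [window_radius()].
#' @return data.table with columns `id`, `x`, `y` (cell-center coordinates),
#'   `height`, `radius`, `row`, `col`. Empty (zero-row) for an all-NA
#'   raster.
#' @export
detect_treetops <- function(chm, slope = 0.16, intercept = 0.8) {
  hits <- .cpp_local_maxima(chm$values, chm$res, slope, intercept)
  cc <- cell_centers(chm)
  h <- chm$values[hits]
  out <- data.table(id = seq_len(nrow(hits)),
                    x = cc$x[hits[, "col"]],
                    y = cc$y[hits[, "row"]],
                    height = h,
                    radius = window_radius(h, slope, intercept),
                    row = hits[, "row"], col = hits[, "col"])
  setattr(out, "crs", chm$crs)
  out[]
}

#' Filter detected tops against unit and NEA layers
#'
#' Keeps only tops that fall inside a forest-stand unit polygon (units whose
#' `land_kind` is not `"stand"` - marshes, meadows, woodlots - reject their
#' tops), then removes tops inside any non-exclusive area dilated by
#' `nea_buffer` meters. Survivors gain the `forest_address` of their
#' containing unit. Counts of tops dropped at each step are attached as
#' `attr(out, "drop_counts")`.
#'
#' @param tops output of [detect_treetops()].
#' @param units a [forest_units()] layer.
#' @param neas optional NEA polygon layer (un-buffered); `NULL` or an empty
#'   layer skips NEA filtering.
#' @param nea_buffer NEA dilation width in m (default 2).
#' @return filtered tops with a `forest_address` column.
#' @export
filter_treetops <- function(tops, units, neas = NULL, nea_buffer = 2) {
  tp <- as.data.table(tops)
  tp[, forest_address := NA_character_]
  stand <- as.data.table(units)[land_kind == "stand"]
  for (i in seq_len(nrow(stand))) {
    g <- stand$geometry[[i]]
    bb <- c(range(g[, 1]), range(g[, 2]))
    cand <- which(is.na(tp$forest_address) &
                  tp$x >= bb[1] & tp$x <= bb[2] &
                  tp$y >= bb[3] & tp$y <= bb[4])
    if (!length(cand)) next
    inside <- point_in_polygon(tp$x[cand], tp$y[cand], g)
    tp[cand[inside], forest_address := stand$forest_address[i]]
  }
  n_outside <- sum(is.na(tp$forest_address))
  tp <- tp[!is.na(forest_address)]
  n_nea <- 0L
  if (!is.null(neas) && nrow(neas)) {
    buffered <- if (nea_buffer > 0) buffer_neas(neas, nea_buffer) else neas
    drop <- rep(FALSE, nrow(tp))
    for (i in seq_len(nrow(buffered))) {
      g <- buffered$geometry[[i]]
      bb <- c(range(g[, 1]), range(g[, 2]))
      cand <- which(!drop & tp$x >= bb[1] & tp$x <= bb[2] &
                    tp$y >= bb[3] & tp$y <= bb[4])
      if (!length(cand)) next
      drop[cand[point_in_polygon(tp$x[cand], tp$y[cand], g)]] <- TRUE
    }
    n_nea <- sum(drop)
    tp <- tp[!drop]
  }
  setattr(tp, "drop_counts",
          c(outside_units = n_outside, in_nea = n_nea))
  tp[]
}
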
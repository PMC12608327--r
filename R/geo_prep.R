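#' Forest-unit vector layers
#'
#' A `forest_units` layer is a [data.table::data.table] with one row per
#' forest unit and a `geometry` list-column of polygon rings (two-column
#' matrices, projected meters). Standard attribute columns:
#' `forest_address` (unique identifier), `epoch`, `dominant_species`,
#' `age` (years), `inventory_height` (whole m, dominant species of the
#' tallest layer), `site_type`, `area_ha`, `land_kind` (`"stand"` or a
#' non-stand category such as `"marsh"` or `"meadow"`).
#'
#' @param attrs data.frame of unit attributes (must contain
#'   `forest_address`).
#' @param geometry list of polygon rings, one per row of `attrs`.
#' @param crs CRS identifier (projected; geographic CRS are refused).
#' @return a `forest_units` object.
#' @export
forest_units <- function(attrs, geometry, crs = "local") {
  dt <- as.data.table(attrs)
  if (!"forest_address" %in% names(dt))
    stop("forest_units needs a forest_address column")
  if (length(geometry) != nrow(dt))
    stop("one geometry per attribute row required")
  if (grepl("^epsg:4326$|wgs84|longlat", tolower(crs)))
    stop("geographic CRS refused; supply projected coordinates in meters")
  dt[, geometry := lapply(geometry, function(g) ring_open(as.matrix(g)))]
  if (!"area_ha" %in% names(dt))
    dt[, area_ha := vapply(geometry, poly_area, 0) / 1e4]
  if (!"land_kind" %in% names(dt)) dt[, land_kind := "stand"]
  setattr(dt, "crs", crs)
  setattr(dt, "class", c("forest_units", class(dt)))
  dt[]
}

#' @export
print.forest_units <- function(x, ...) {
  cat(sprintf("<forest_units> %d units, crs '%s', %.2f ha\n",
              nrow(x), attr(x, "crs"), sum(x$area_ha)))
  NextMethod()
}

#' Read / write polygon layers as GeoJSON
#'
#' Minimal GeoJSON (RFC 7946 structure) support for `Polygon` features:
#' feature properties become attribute columns, the outer ring becomes the
#' `geometry` entry. Holes and multipolygons are not handled.
#'
#' @param units a [forest_units()] layer.
#' @param path file path.
#' @return `write_units_geojson` returns `path` invisibly;
#'   `read_units_geojson` returns a [forest_units()] layer.
#' @export
write_units_geojson <- function(units, path) {
  feats <- lapply(seq_len(nrow(units)), function(i) {
    ring <- ring_close(units$geometry[[i]])
    props <- as.list(as.data.table(units)[i, !"geometry"])
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) ring[k, ]))))
  })
  fc <- list(type = "FeatureCollection",
             crs = attr(units, "crs"),
             features = feats)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}

#' @rdname write_units_geojson
#' @export
read_units_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path)
  crs <- fc$crs %||% "local"
  feats <- fc$features
  if (!length(feats))
    return(forest_units(data.table(forest_address = character()),
                        list(), crs = crs))
  props <- rbindlist(lapply(feats, function(f)
    as.data.table(lapply(f$properties, function(v) v %||% NA))),
    fill = TRUE)
  geoms <- lapply(feats, function(f) {
    co <- f$geometry$coordinates[[1]]
    do.call(rbind, lapply(co, function(p) c(p[[1]], p[[2]])))
  })
  forest_units(props, geoms, crs = crs)
}

#' Harmonize an epoch's inventory layer to the common schema
#'
#' Brings one epoch of forest-documentation data into the single analysis
#' schema: joins an external stand-height table (per-species, per-layer rows)
#' where the layer geometry lacks heights, keeps only the tallest layer and
#' the dominant species, attaches forest addresses from an auxiliary table
#' when given, tags the epoch, and excludes stands whose inventory height is
#' at or below `min_height` (growth tabulations start above 6 m, so lower
#' stands carry no usable height signal). Units whose join key finds no
#' match are not silently dropped: they are listed in the rejects report
#' attached as `attr(out, "rejects")` (columns `forest_address`, `reason`).
#'
#' @param units a [forest_units()] layer.
#' @param height_table optional data.frame with columns `forest_address`,
#'   `species`, `height` and optionally `layer` (1 = top storey).
#' @param address_table optional data.frame with columns `id`,
#'   `forest_address` keyed to a unit `id` column.
#' @param epoch epoch tag stored on every row.
#' @param min_height exclusion threshold in m (default 6; rule: height <=
#'   `min_height` is rejected).
#' @return harmonized [forest_units()] layer with a rejects report
#'   attribute.
#' @export
harmonize_layers <- function(units, height_table = NULL,
                             address_table = NULL, epoch = NA_character_,
                             min_height = 6) {
  out <- as.data.table(units)
  rejects <- data.table(forest_address = character(), reason = character())
  if (!is.null(address_table)) {
    at <- as.data.table(address_table)
    out <- merge(out, at, by = "id", all.x = TRUE, suffixes = c("", ".addr"))
    if ("forest_address.addr" %in% names(out)) {
      out[is.na(forest_address), forest_address := forest_address.addr]
      out[, forest_address.addr := NULL]
    }
    miss <- out[is.na(forest_address)]
    if (nrow(miss)) {
      rejects <- rbind(rejects, data.table(
        forest_address = paste0("id:", miss$id), reason = "unmatched_address"))
      out <- out[!is.na(forest_address)]
    }
  }
  if (!is.null(height_table)) {
    ht <- as.data.table(height_table)
    if ("layer" %in% names(ht)) ht <- ht[layer == 1L | is.na(layer)]
    ht <- ht[, .(forest_address, species, height)]
    out <- merge(out, ht, by = "forest_address", all.x = TRUE,
                 allow.cartesian = TRUE)
    # only the dominant species' height is retained
    out <- out[is.na(species) | species == dominant_species]
    out[, inventory_height := height]
    out[, c("species", "height") := NULL]
    nohit <- out[is.na(inventory_height), forest_address]
    if (length(nohit))
      rejects <- rbind(rejects, data.table(forest_address = nohit,
                                           reason = "unmatched_height"))
  }
  if (!"inventory_height" %in% names(out))
    out[, inventory_height := NA_real_]
  low <- out[!is.na(inventory_height) & inventory_height <= min_height,
             forest_address]
  if (length(low)) {
    rejects <- rbind(rejects, data.table(forest_address = low,
                                         reason = "height_le_threshold"))
    out <- out[!forest_address %in% low]
  }
  out[, epoch := epoch]
  res <- forest_units(out[, !"geometry"], out$geometry,
                      crs = attr(units, "crs"))
  setattr(res, "rejects", rejects)
  res
}

#' Buffer non-exclusive areas
#'
#' Dilates every NEA polygon by `width` meters with round joins. NEAs are
#' digitized in the field with consumer-grade GNSS; the default 2 m buffer
#' (half the crown width of a mature Scots pine) absorbs their positional
#' error before tree tops are filtered against them.
#'
#' @param neas a [forest_units()]-style layer of NEA polygons.
#' @param width buffer width in m (>= 0).
#' @return layer with dilated geometries and updated `area_ha`.
#' @export
buffer_neas <- function(neas, width = 2) {
  stopifnot(width >= 0)
  out <- as.data.table(neas)
  if (!nrow(out)) return(neas)
  out[, geometry := lapply(geometry, buffer_polygon, width = width)]
  out[, area_ha := vapply(geometry, poly_area, 0) / 1e4]
  res <- forest_units(out[, !"geometry"], out$geometry,
                      crs = attr(neas, "crs"))
  res
}

#' Match forest units across two survey epochs
#'
#' Unit addresses drift between forest-management-plan revisions, so units
#' are matched spatially, never by address string: every pair of
#' intersecting polygons is intersected, and a fragment is kept only when it
#' contains the pole of inaccessibility of the current-epoch (second) unit.
#' That single containment rule discards the sliver fragments that polygon
#' overlay generates along revised boundaries, without any ad hoc area
#' threshold. Each current-epoch unit therefore matches at most one
#' earlier-epoch unit.
#'
#' Current-epoch geometries must be convex (the clipping step requires a
#' convex clip ring); survey-revision fragments of arbitrary shape are
#' supported on the earlier-epoch side.
#'
#' @param units_old,units_new [forest_units()] layers of the earlier and
#'   current epoch in one CRS.
#' @param precision pole-of-inaccessibility precision in m.
#' @return data.table with one row per matched pair: addresses, ages,
#'   heights and areas of both epochs, `overlap_area_ha`, and the overlap
#'   ring in the `overlap` list-column. Unmatched current-epoch units are
#'   reported in `attr(out, "unmatched")`.
#' @export
match_units <- function(units_old, units_new, precision = 0.1) {
  if (!identical(attr(units_old, "crs"), attr(units_new, "crs")))
    stop("layers must share a CRS")
  old <- as.data.table(units_old)
  new <- as.data.table(units_new)
  grab <- function(dt, col) if (col %in% names(dt)) dt[[col]] else
    rep(NA_real_, nrow(dt))
  bbox <- function(g) c(range(g[, 1]), range(g[, 2]))
  bb_old <- lapply(old$geometry, bbox)
  rows <- vector("list", nrow(new))
  unmatched <- character(0)
  for (j in seq_len(nrow(new))) {
    gnew <- new$geometry[[j]]
    pole <- pole_of_inaccessibility(gnew, precision = precision)
    bbn <- bbox(gnew)
    hit <- NULL
    for (i in seq_len(nrow(old))) {
      bbo <- bb_old[[i]]
      if (bbo[1] > bbn[2] || bbo[2] < bbn[1] ||
          bbo[3] > bbn[4] || bbo[4] < bbn[3]) next
      frag <- clip_polygon(old$geometry[[i]], gnew)
      if (is.null(frag)) next
      if (point_in_polygon(pole[["x"]], pole[["y"]], frag)) {
        hit <- list(i = i, frag = frag)
        break
      }
    }
    if (is.null(hit)) {
      unmatched <- c(unmatched, new$forest_address[j])
      next
    }
    i <- hit$i
    rows[[j]] <- data.table(
      address_old = old$forest_address[i],
      address_new = new$forest_address[j],
      age_old = grab(old, "age")[i],
      age_new = grab(new, "age")[j],
      height_old = grab(old, "inventory_height")[i],
      height_new = grab(new, "inventory_height")[j],
      area_old_ha = old$area_ha[i],
      area_new_ha = new$area_ha[j],
      overlap_area_ha = poly_area(hit$frag) / 1e4,
      overlap = list(hit$frag))
  }
  out <- rbindlist(rows[!vapply(rows, is.null, TRUE)])
  setattr(out, "unmatched", unmatched)
  out[]
}

#' Filter matched unit pairs for increment analysis
#'
#' Removes pairs that cannot carry a meaningful height increment: a negative
#' age difference between the epochs signals a clear-cut and replanting, and
#' a unit with no trees (missing inventory height) in the earlier epoch has
#' no base height. Pairs with missing age in either epoch are dropped with
#' their own reason code.
#'
#' @param matches output of [match_units()].
#' @return filtered data.table; dropped pairs with reason codes in
#'   `attr(out, "rejects")`.
#' @export
filter_matched <- function(matches) {
  m <- as.data.table(matches)
  reason <- rep(NA_character_, nrow(m))
  reason[is.na(m$age_old) | is.na(m$age_new)] <- "missing_age"
  ok <- is.na(reason)
  reason[ok & (m$age_new - m$age_old < 0)] <- "negative_age_difference"
  ok <- is.na(reason)
  reason[ok & is.na(m$height_old)] <- "treeless_first_epoch"
  keep <- is.na(reason)
  out <- m[keep]
  setattr(out, "rejects",
          data.table(address_new = m$address_new[!keep],
                     reason = reason[!keep]))
  out[]
}
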
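two_epoch_layers <- function() {
  mk <- function(addresses, rings, ages, heights, epoch) {
    forest_units(data.table(forest_address = addresses,
                            dominant_species = "pine",
                            site_type = "FPF",
                            age = ages,
                            inventory_height = heights,
                            land_kind = "stand",
                            epoch = epoch),
                 rings, crs = "EPSG:2180")
  }
  old <- mk(c("13-A", "13-B", "13-C"),
            list(square_ring(0, 0, 50), square_ring(50, 0, 50),
                 square_ring(0, 50, 50)),
            ages = c(60, 55, 40), heights = c(18, 20, 15), epoch = "2013")
  # 2022: A and B merged into one unit, C unchanged (address drifted)
  new <- mk(c("22-AB", "22-C"),
            list(cbind(c(0, 100, 100, 0), c(0, 0, 50, 50)),
                 square_ring(0, 50, 50)),
            ages = c(64, 49), heights = c(20, 17), epoch = "2022")
  list(old = old, new = new)
}

test_that("harmonization joins heights, keeps dominant species, rejects low stands", {
  units <- forest_units(
    data.table(forest_address = c("A", "B", "C"),
               dominant_species = c("pine", "pine", "birch"),
               age = c(60, 20, 35), land_kind = "stand"),
    list(square_ring(0, 0, 10), square_ring(10, 0, 10),
         square_ring(20, 0, 10)),
    crs = "EPSG:2180")
  heights <- data.table(
    forest_address = c("A", "A", "A", "B", "C"),
    species = c("pine", "birch", "spruce", "pine", "birch"),
    height = c(21, 14, 17, 5, 12),
    layer = 1L)
  h <- harmonize_layers(units, heights, epoch = "2013")
  expect_equal(nrow(h), 2)                       # B rejected: height <= 6
  expect_equal(h[h$forest_address == "A", ]$inventory_height, 21)  # pine only
  expect_equal(h[h$forest_address == "C", ]$inventory_height, 12)
  expect_equal(unique(h$epoch), "2013")
  rej <- attr(h, "rejects")
  expect_true("B" %in% rej$forest_address)
  expect_equal(rej[rej$forest_address == "B", ]$reason,
               "height_le_threshold")

  # unmatched join key lands in the rejects report, not silently dropped
  h2 <- harmonize_layers(units, heights[forest_address != "C"],
                         epoch = "2013")
  expect_true("C" %in% attr(h2, "rejects")$forest_address)
})

test_that("NEA buffering dilates each polygon and survives empty layers", {
  nea <- forest_units(data.table(forest_address = "N1", land_kind = "nea"),
                      list(square_ring(0, 0, 10)), crs = "EPSG:2180")
  b <- buffer_neas(nea, 2)
  expect_equal(b$area_ha * 1e4, 100 + 80 + 4 * pi, tolerance = 0.05)
  expect_equal(buffer_neas(nea, 0)$area_ha, nea$area_ha)
  empty <- forest_units(data.table(forest_address = character(),
                                   land_kind = character()),
                        list(), crs = "EPSG:2180")
  expect_equal(nrow(buffer_neas(empty, 2)), 0)
})

test_that("cross-epoch matching uses pole containment, not addresses", {
  ly <- two_epoch_layers()
  m <- match_units(ly$old, ly$new)
  expect_equal(nrow(m), 2)
  # merged 2022 unit matches whichever 2013 half contains its pole
  ab <- m[m$address_new == "22-AB", ]
  pole <- pole_of_inaccessibility(ly$new$geometry[[1]])
  expect_true(ab$address_old %in% c("13-A", "13-B"))
  in_a <- point_in_polygon(pole[["x"]], pole[["y"]], ly$old$geometry[[1]])
  expect_equal(ab$address_old, if (in_a) "13-A" else "13-B")
  expect_equal(m[m$address_new == "22-C", ]$address_old, "13-C")
  # overlap never exceeds either parent
  expect_true(all(m$overlap_area_ha <=
                    pmin(m$area_old_ha, m$area_new_ha) + 1e-9))
  # identical layers match one-to-one with full overlap
  ident <- match_units(ly$old, ly$old)
  expect_equal(nrow(ident), 3)
  expect_equal(ident$overlap_area_ha, ident$area_old_ha, tolerance = 1e-9)
  # determinism under input reordering
  m2 <- match_units(ly$old[c(3, 1, 2)], ly$new)
  setkey(m, address_new); setkey(m2, address_new)
  expect_equal(m$address_old, m2$address_old)
})

test_that("boundary-contact units do not match", {
  a <- one_unit(square_ring(0, 0, 10), "A")
  b <- one_unit(square_ring(10, 0, 10), "B")
  m <- match_units(a, b)
  expect_equal(nrow(m), 0)
  expect_equal(attr(m, "unmatched"), "B")
})

test_that("pair filtering drops clear-cuts and treeless origins", {
  base <- data.table(address_old = c("a", "b", "c", "d"),
                     address_new = c("A", "B", "C", "D"),
                     age_old = c(60, 60, NA, 50),
                     age_new = c(69, 5, 60, 59),
                     height_old = c(18, 20, 19, NA),
                     height_new = c(20, 8, 21, 9),
                     overlap_area_ha = 1)
  f <- filter_matched(base)
  expect_equal(f$address_new, "A")
  rej <- attr(f, "rejects")
  expect_equal(rej[rej$address_new == "B", ]$reason,
               "negative_age_difference")
  expect_equal(rej[rej$address_new == "C", ]$reason, "missing_age")
  expect_equal(rej[rej$address_new == "D", ]$reason,
               "treeless_first_epoch")
})

test_that("GeoJSON layers round-trip attributes and rings", {
  ly <- two_epoch_layers()$old
  path <- withr::local_tempfile(fileext = ".geojson")
  write_units_geojson(ly, path)
  back <- read_units_geojson(path)
  expect_equal(back$forest_address, ly$forest_address)
  expect_equal(back$inventory_height, ly$inventory_height)
  expect_equal(back$geometry[[2]], ly$geometry[[2]], tolerance = 1e-9)
  expect_error(forest_units(data.table(forest_address = "x"),
                            list(square_ring()), crs = "EPSG:4326"),
               "geographic")
})
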
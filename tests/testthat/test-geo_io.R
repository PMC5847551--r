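test_that("grid_spec validates and derives pixel area from its fields", {
  g <- grid_spec(10, 20, pixel_width = 2, pixel_height = 3)
  expect_equal(pixel_area(g), 6)
  expect_error(grid_spec(0, 10), "positive")
  expect_error(grid_spec(10, 10, pixel_width = -1), "positive")
})

test_that("pixel/map coordinate conversions are inverse and half-open", {
  g <- grid_spec(16, 16, pixel_width = 2, origin_x = 100, origin_y = 200)
  ctr <- pixel_centers(g, row = c(0, 15), col = c(0, 15))
  px <- map_to_pixel(g, ctr[, 1], ctr[, 2])
  expect_equal(px, cbind(row = c(0L, 15L), col = c(0L, 15L)))
  # shared edge belongs to the larger-index pixel
  edge <- map_to_pixel(g, 100 + 2, 200 - 2)  # corner between 4 pixels
  expect_equal(unname(edge), cbind(1L, 1L), ignore_attr = TRUE)
  outside <- map_to_pixel(g, 99, 200)
  expect_true(anyNA(outside))
})

test_that("ASCII grid round-trip preserves DN and GridSpec", {
  set.seed(11)
  g <- grid_spec(12, 9, pixel_width = 1000, origin_x = -5e5, origin_y = 3e5)
  dn <- matrix(round(runif(12 * 9, 0, 63), 3), 12, 9)
  dn[3, 4] <- NA
  cg <- composite_grid(dn, g, 1999, "F12")
  path <- withr::local_tempfile(fileext = ".asc")
  write_asc(cg, path)
  back <- read_asc(path, 1999, "F12")
  expect_equal(back$dn, cg$dn, tolerance = 1e-9)
  expect_true(nightrange:::grids_identical(back$grid, g))
  expect_identical(back$year, 1999L)
})

test_that("read_asc clips out-of-range DN with a warning", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("NCOLS 2", "NROWS 2", "XLLCORNER 0", "YLLCORNER 0",
               "CELLSIZE 1", "NODATA_VALUE -9999",
               "70 5", "-3 63"), path)
  expect_warning(g <- read_asc(path, 2000), "clipped")
  expect_equal(g$dn, matrix(c(63, 0, 5, 63), 2, 2))
})

test_that("read_stack orders years and rejects mismatched grids", {
  d <- withr::local_tempdir()
  g <- grid_spec(8, 8)
  paths <- character(3); yrs <- c(1994L, 1992L, 1993L)
  for (i in 1:3)
    paths[i] <- write_asc(flat_grid(i, year = yrs[i]),
                          file.path(d, sprintf("y%d.asc", i)))
  stack <- read_stack(paths, yrs)
  expect_equal(nightrange:::stack_years(stack), c(1992L, 1993L, 1994L))
  expect_length(read_stack(paths[1], yrs[1]), 1)  # single year accepted
  # a raster on a different pixel size is a grid mismatch
  other <- composite_grid(matrix(1, 8, 8), grid_spec(8, 8, pixel_width = 2),
                          1995)
  p4 <- write_asc(other, file.path(d, "y4.asc"))
  expect_error(read_stack(c(paths, p4), c(yrs, 1995L)), "grid mismatch")
  expect_error(read_stack(paths, c(1992L, 1992L, 1994L)), "unique")
})

test_that("species ranges round-trip through GeoJSON with attributes", {
  ring <- rbind(c(0, 0), c(4, 0), c(4, 3), c(0, 3))
  r1 <- species_range("spA", ring, name = "Alpha", category = "EN",
                      used = TRUE, use_categories = c("food (human)"))
  hole <- rbind(c(1, 1), c(2, 1), c(2, 2), c(1, 2))
  r2 <- species_range("spB", list(list(close_ring_ <- ring, hole)),
                      category = "LC", used = FALSE)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_ranges(list(r1, r2), path)
  back <- load_ranges(path)
  expect_length(back, 2)
  expect_identical(back[[1]]$species_id, "spA")
  expect_identical(back[[1]]$name, "Alpha")
  expect_true(back[[1]]$threatened)   # EN is a threatened category
  expect_false(back[[2]]$threatened)  # LC is not
  expect_true(back[[1]]$used)
  expect_equal(back[[2]]$geometry[[1]][[2]],
               r2$geometry[[1]][[2]], tolerance = 1e-12)
})

test_that("load_ranges enforces schema, rejects empty geometry, flags dupes", {
  path <- withr::local_tempfile(fileext = ".geojson")
  fc <- list(type = "FeatureCollection", features = list(
    list(type = "Feature",
         properties = list(species_id = "a", category = "LC", used = FALSE),
         geometry = list(type = "Polygon", coordinates = list())),
    list(type = "Feature",
         properties = list(species_id = "b", category = "VU", used = TRUE),
         geometry = list(type = "Polygon", coordinates = list(
           list(list(0, 0), list(2, 0), list(2, 2), list(0, 2)))))))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  expect_warning(rng <- load_ranges(path), "a")
  expect_length(rng, 1)
  fc$features[[1]]$properties$used <- NULL
  fc$features[[1]]$geometry <- fc$features[[2]]$geometry
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  expect_error(suppressWarnings(load_ranges(path)), "used")
  fc$features[[1]]$properties <- fc$features[[2]]$properties
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  expect_error(suppressWarnings(load_ranges(path)), "duplicate")
})

test_that("rasterization follows the pixel-center rule on exact blocks", {
  g <- grid_spec(10, 10)
  # rectangle exactly covering a 3 x 4 pixel block -> 12 pixels
  ring <- rbind(c(2, 10 - 3), c(6, 10 - 3), c(6, 10 - 6), c(2, 10 - 6))
  m <- rasterize_range(species_range("r", ring), g)
  expect_equal(m$n_pixels, 12L)
  expect_setequal(m$pixels[, "col"], 2:5)
  expect_setequal(m$pixels[, "row"], 3:5)
})

test_that("sub-pixel polygons fall back to the centroid pixel", {
  g <- grid_spec(10, 10)
  tiny <- rbind(c(4.1, 5.1), c(4.3, 5.1), c(4.3, 5.3), c(4.1, 5.3))
  m <- rasterize_range(species_range("tiny", tiny), g)
  expect_equal(m$n_pixels, 1L)
  expect_equal(unname(m$pixels[1, ]), c(4L, 4L))  # centroid (4.2, 5.2)
  far <- tiny + 100
  expect_error(rasterize_range(species_range("far", far), g), "outside")
})

test_that("L-shaped polygon matches the exhaustive center-in-polygon oracle", {
  g <- grid_spec(12, 12)
  L <- rbind(c(1, 11), c(7, 11), c(7, 8), c(4, 8), c(4, 2), c(1, 2))
  m <- rasterize_range(species_range("L", L), g)
  oracle <- oracle_rasterize(close_ring_l <- rbind(L, L[1, ]), g)
  got <- m$pixels[order(m$pixels[, 1], m$pixels[, 2]), , drop = FALSE]
  want <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
  expect_equal(unname(got), unname(want))
})

test_that("rasterization equals the oracle on seeded random polygons", {
  set.seed(314)
  g <- grid_spec(32, 32)
  for (i in 1:40) {
    ring <- random_polygon(g, max_r = 10)
    m <- rasterize_range(species_range(paste0("p", i), ring), g)
    oracle <- oracle_rasterize(ring, g)
    if (is.null(oracle)) {
      expect_equal(m$n_pixels, 1L)  # centroid fallback
    } else {
      got <- m$pixels[order(m$pixels[, 1], m$pixels[, 2]), , drop = FALSE]
      want <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
      expect_equal(unname(got), unname(want))
    }
  }
})

test_that("pixel count times pixel area approximates convex polygon area", {
  set.seed(99)
  g <- grid_spec(48, 48, pixel_width = 2)
  for (i in 1:20) {
    pts <- cbind(runif(12, 10, 80), runif(12, 10, 80))
    hull <- pts[chull(pts), , drop = FALSE]
    ring <- rbind(hull, hull[1, ])
    m <- rasterize_range(species_range(paste0("c", i), ring), g)
    area_est <- m$n_pixels * pixel_area(g)
    band <- ring_perimeter(ring) * sqrt(2) * g$pixel_width
    expect_lt(abs(area_est - ring_area(ring)), band)
  }
})

test_that("range masks validate bounds and export to CSV", {
  g <- grid_spec(8, 8)
  expect_error(range_mask("x", cbind(8, 0), g), "outside")
  expect_error(range_mask("x", matrix(integer(), 0, 2), g), "empty")
  m <- range_mask("x", rbind(c(0, 0), c(7, 7)), g)
  path <- withr::local_tempfile(fileext = ".csv")
  write_masks_csv(list(m), path)
  df <- read.csv(path)
  expect_equal(df$row, c(0L, 7L))
  expect_equal(df$col, c(0L, 7L))
})
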
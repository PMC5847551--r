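test_that("nightscape_params validates its invariants", {
  expect_error(nightscape_params(grid_rows = 8), ">= 16")
  expect_error(nightscape_params(n_years = 2), "n_years")
  expect_error(nightscape_params(noise_sd = -1), "noise_sd")
  expect_error(nightscape_params(growth_rate = -0.1), "growth_rate")
})

test_that("nightscape generation is deterministic and bounded", {
  p <- nightscape_params(grid_rows = 32, grid_cols = 32, n_years = 4,
                         n_urban_seeds = 3, noise_sd = 1.5, seed = 5)
  a <- make_nightscape(p)
  b <- make_nightscape(p)
  expect_identical(lapply(a, `[[`, "dn"), lapply(b, `[[`, "dn"))
  for (g in a) {
    expect_true(all(g$dn >= 0 & g$dn <= 63))
    expect_true(all(g$dn == round(g$dn)))  # true DN are integers
  }
  expect_equal(nightrange:::stack_years(a), 1992:1995)
})

test_that("no growth and no noise give identical years; no seeds give darkness", {
  p0 <- nightscape_params(grid_rows = 24, grid_cols = 24, n_years = 3,
                          n_urban_seeds = 2, growth_rate = 0, noise_sd = 0,
                          seed = 2)
  s <- make_nightscape(p0)
  expect_identical(s[[1]]$dn, s[[2]]$dn)
  expect_identical(s[[1]]$dn, s[[3]]$dn)
  dark <- make_nightscape(nightscape_params(grid_rows = 24, grid_cols = 24,
                                            n_years = 3, n_urban_seeds = 0,
                                            seed = 2))
  expect_true(all(vapply(dark, function(g) all(g$dn == 0), logical(1))))
})

test_that("lit area and total DN are non-decreasing under noiseless growth", {
  p <- nightscape_params(grid_rows = 48, grid_cols = 48, n_years = 21,
                         n_urban_seeds = 4, growth_rate = 0.05, noise_sd = 0,
                         seed = 3)
  s <- make_nightscape(p)
  lit <- vapply(s, function(g) sum(g$dn >= 5.5), numeric(1))
  tot <- vapply(s, function(g) sum(g$dn), numeric(1))
  expect_true(all(diff(lit) >= 0))
  expect_true(all(diff(tot) >= 0))
  expect_gt(lit[21], lit[1])  # growth actually happens
  # urban cores saturate
  expect_true(any(s[[1]]$dn == 63))
})

test_that("apply_distortion evaluates the polynomial, clamps and keeps zeros", {
  g <- flat_grid(0, 4, 4)
  g$dn[1, 1] <- 60; g$dn[2, 2] <- 30
  ident <- apply_distortion(g, 0, 1, 0)
  expect_identical(ident$dn, g$dn)
  shifted <- apply_distortion(g, 10, 1, 0)
  expect_equal(shifted$dn[1, 1], 63)      # clamp at 63
  expect_equal(shifted$dn[4, 4], 0)       # true darkness never lit
  poly <- apply_distortion(g, -1, 1.2, -0.003)
  expect_equal(poly$dn[2, 2], 32.3)       # -1 + 1.2*30 - 0.003*900
  noisy <- apply_distortion(g, 0, 1, 0, noise_sd = 2, seed = 7)
  expect_equal(noisy$dn[4, 4], 0)
  expect_identical(noisy$dn, apply_distortion(g, 0, 1, 0, noise_sd = 2,
                                              seed = 7)$dn)
})

test_that("distortion_spec requires an identity year and valid noise", {
  expect_error(distortion_spec(c(1, 2), c(1, 1), c(0, 0)), "identity")
  expect_error(distortion_spec(0, 1, 0, noise_sd = -1), "noise_sd")
  sp <- random_distortion_spec(7, seed = 10)
  mid <- 4
  expect_equal(c(sp$c0[mid], sp$c1[mid], sp$c2[mid]), c(0, 1, 0))
  expect_error(distort_stack(make_nightscape(nightscape_params(
    grid_rows = 16, grid_cols = 16, n_years = 3, seed = 1)), sp), "match")
})

test_that("range_params validates fractions and sizes", {
  expect_error(range_params(frac_used = 1.2), "fractions")
  expect_error(range_params(range_size_min = 0), "range_size_min")
  expect_error(range_params(range_size_max = 0.5), "range_size_max")
  expect_error(make_ranges(range_params(range_size_max = 1e6),
                           grid_spec(64, 64)), "exceeds grid area")
})

test_that("make_ranges honours counts, bounds, flags and determinism", {
  g <- grid_spec(64, 64)
  one <- make_ranges(range_params(n_species = 1, range_size_max = 100,
                                  seed = 5), g)
  expect_length(one$ranges, 1)
  expect_gte(one$masks[[1]]$n_pixels, 1)
  expect_lte(one$masks[[1]]$n_pixels, 100)
  all_used <- make_ranges(range_params(n_species = 20, frac_used = 1,
                                       range_size_max = 50, seed = 6), g)
  expect_true(all(vapply(all_used$ranges, `[[`, logical(1), "used")))
  again <- make_ranges(range_params(n_species = 20, frac_used = 1,
                                    range_size_max = 50, seed = 6), g)
  expect_identical(lapply(again$masks, `[[`, "pixels"),
                   lapply(all_used$masks, `[[`, "pixels"))
  # threatened flag is derivable from the category
  rs <- make_ranges(range_params(n_species = 60, range_size_max = 50,
                                 seed = 7), g)
  for (r in rs$ranges)
    expect_identical(r$threatened, r$category %in% c("CR", "EN", "VU"))
})

test_that("used fraction matches its target in expectation over seeds", {
  g <- grid_spec(32, 32)
  fracs <- vapply(1:10, function(s) {
    rs <- make_ranges(range_params(n_species = 200, range_size_max = 64,
                                   seed = s), g)
    mean(vapply(rs$ranges, `[[`, logical(1), "used"))
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 838 / 1435), 0.05)
})

test_that("make_dataset bundles observed, truth, ranges and a valid truth table", {
  b <- small_bundle()
  expect_s3_class(b, "nightrange_bundle")
  tt <- b$truth_exposure
  expect_true(all(tt$prop_lit >= 0 & tt$prop_lit <= 1))
  expect_true(all(tt$n_lit <= tt$n_pixels))
  expect_equal(nrow(tt), 30 * 8)
  # identity distortion: observed equals truth
  ns <- nightscape_params(grid_rows = 24, grid_cols = 24, n_years = 3,
                          n_urban_seeds = 2, seed = 9)
  ident <- make_dataset(ns, NULL, range_params(n_species = 3,
                                               range_size_max = 30,
                                               seed = 10))
  expect_identical(lapply(ident$observed, `[[`, "dn"),
                   lapply(ident$truth, `[[`, "dn"))
  # ground truth table is computed on the TRUE stack: identity vs distorted
  # bundles from the same seeds share it
  dist <- make_dataset(ns, random_distortion_spec(3, noise_sd = 2, seed = 11),
                       range_params(n_species = 3, range_size_max = 30,
                                    seed = 10))
  expect_equal(dist$truth_exposure, ident$truth_exposure)
})

test_that("bundle export writes text formats that reload consistently", {
  b <- small_bundle()
  d <- withr::local_tempdir()
  export_bundle(b, d)
  files <- list.files(d)
  expect_true("ranges.geojson" %in% files)
  expect_true("truth_exposure.csv" %in% files)
  expect_true("bundle_config.json" %in% files)
  obs <- read_asc(file.path(d, "observed_1992.asc"), 1992)
  expect_equal(obs$dn, b$observed[[1]]$dn, tolerance = 1e-9)
  rng <- load_ranges(file.path(d, "ranges.geojson"))
  expect_length(rng, length(b$ranges$ranges))
  # rasterizing the exported polygon recovers the analytic mask closely
  m0 <- b$ranges$masks[[which.max(vapply(b$ranges$masks, `[[`,
                                         integer(1), "n_pixels"))]]
  r0 <- rng[[match(m0$species_id,
                   vapply(rng, `[[`, character(1), "species_id"))]]
  m1 <- rasterize_range(r0, b$truth[[1]]$grid)
  common <- nrow(merge(as.data.frame(m0$pixels), as.data.frame(m1$pixels)))
  expect_gt(common / m0$n_pixels, 0.95)
})
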
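# Shared small fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# 64 x 64, 8 years, 30 species: big enough to exercise every stage, small
# enough to build in about a second.
small_bundle <- function() {
  if (is.null(fixture_env$small_bundle)) {
    ns <- nightscape_params(grid_rows = 64, grid_cols = 64, n_years = 8,
                            n_urban_seeds = 5, growth_rate = 0.08, seed = 42)
    fixture_env$small_bundle <- make_dataset(
      ns, random_distortion_spec(8, seed = 43),
      range_params(n_species = 30, range_size_max = 400, seed = 44))
  }
  fixture_env$small_bundle
}

# Uniform DN grid helper.
flat_grid <- function(value, rows = 8, cols = 8, year = 2000) {
  composite_grid(matrix(value, rows, cols), grid_spec(rows, cols), year)
}

mask_from_pixels <- function(pixels, grid, id = "sp") {
  range_mask(id, pixels, grid)
}
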
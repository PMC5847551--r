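#' @section Reproducibility:
#' All generators take explicit integer seeds and restore the caller's RNG
#' state on exit, so no global random state leaks between calls.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Parameters for the synthetic nightscape generator
#'
#' The generator emulates the gross structure of annual stable-lights
#' composites: a handful of urban light sources with saturated cores (DN 63),
#' brightness decaying linearly with distance from the core so that the dim
#' periphery straddles the 5.5 DN darkness threshold, and a secular expansion
#' of the lit footprint over the years. By default the light sources are
#' confined to the eastern part of the grid so that a species-richness
#' gradient placed in the west is negatively associated with brightness.
#'
#' @param grid_rows,grid_cols Grid dimensions in pixels (each >= 16).
#' @param n_years Number of annual composites (>= 3; default 21,
#'   a 1992-2012-style span).
#' @param n_urban_seeds Number of urban light sources (0 allowed: dark world).
#' @param growth_rate Fractional expansion of the lit *area* per year
#'   (>= 0); the lit radius of every source grows by
#'   `sqrt(1 + growth_rate)` annually.
#' @param base_brightness_decay DN lost per pixel of distance beyond the
#'   saturated core (> 0).
#' @param core_radius Radius (pixels) of the fully saturated (DN 63) core.
#' @param fringe_dn DN of the dim expanding fringe (default 8, above the 5.5
#'   darkness threshold so newly lit pixels count as lit).
#' @param noise_sd Standard deviation (DN) of additive noise applied to lit
#'   pixels of the *true* stack (>= 0; default 0 so that ground truth is
#'   noise-free and monotone).
#' @param light_region Fractions `c(xmin, xmax, ymin, ymax)` of the grid in
#'   which urban seeds are placed. The default eastern band `[0.75, 1]` keeps
#'   even the final-year lit footprint east of the default richness-hotspot
#'   cores (whose x stops at 0.6), so light falls preferentially on
#'   low-richness cells for any seed while the eastern tails of the species
#'   clusters still overlap it.
#' @param start_year First calendar year of the stack.
#' @param seed Integer seed.
#' @return An object of class `nightscape_params`.
#' @export
nightscape_params <- function(grid_rows = 256, grid_cols = 256, n_years = 21,
                              n_urban_seeds = 25, growth_rate = 0.05,
                              base_brightness_decay = 2.5, core_radius = 2,
                              fringe_dn = 8, noise_sd = 0,
                              light_region = c(0.75, 1, 0, 1),
                              start_year = 1992L, seed = 1L) {
  if (grid_rows < 16 || grid_cols < 16)
    stop("grid dimensions must be >= 16", call. = FALSE)
  if (n_years < 3) stop("n_years must be >= 3", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (growth_rate < 0) stop("growth_rate must be >= 0", call. = FALSE)
  if (n_urban_seeds < 0) stop("n_urban_seeds must be >= 0", call. = FALSE)
  if (base_brightness_decay <= 0)
    stop("base_brightness_decay must be > 0", call. = FALSE)
  if (fringe_dn < 0 || fringe_dn > 63)
    stop("fringe_dn must lie in [0, 63]", call. = FALSE)
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 n_years = as.integer(n_years),
                 n_urban_seeds = as.integer(n_urban_seeds),
                 growth_rate = growth_rate,
                 base_brightness_decay = base_brightness_decay,
                 core_radius = core_radius,
                 fringe_dn = fringe_dn,
                 noise_sd = noise_sd,
                 light_region = light_region,
                 start_year = as.integer(start_year),
                 seed = as.integer(seed)),
            class = "nightscape_params")
}

#' Generate a true (undistorted) nightscape stack
#'
#' Each urban seed emits a radially decaying brightness profile: DN 63 inside
#' `core_radius`, then `63 - decay * (d - core_radius)` down to `fringe_dn`,
#' with `d` the distance in pixels. Overlapping sources combine by maximum.
#' The bright interior is *stable over time* — as in real stable-lights
#' composites, where intercalibration leans on unchanged areas — while
#' growth happens at the periphery: a dim fringe at `fringe_dn` extends each
#' source's lit radius so that the lit area grows by a factor
#' `(1 + growth_rate)` per year. Every pixel's DN is therefore non-decreasing
#' in time. True DN are integers in `[0, 63]`.
#'
#' @param params A [nightscape_params()].
#' @return A year-ordered list of [composite_grid()] objects.
#' @export
make_nightscape <- function(params) {
  stopifnot(inherits(params, "nightscape_params"))
  p <- params
  grid <- grid_spec(p$grid_rows, p$grid_cols)
  with_seed(p$seed, {
    if (p$n_urban_seeds > 0) {
      lr <- p$light_region
      sx <- runif(p$n_urban_seeds, lr[1] * p$grid_cols, lr[2] * p$grid_cols)
      sy <- runif(p$n_urban_seeds, lr[3] * p$grid_rows, lr[4] * p$grid_rows)
      px <- matrix(rep(seq_len(p$grid_cols) - 0.5, each = p$grid_rows),
                   nrow = p$grid_rows)
      py <- matrix(rep(seq_len(p$grid_rows) - 0.5, times = p$grid_cols),
                   nrow = p$grid_rows)
      # profile is decreasing in distance, so max over seeds = profile(dmin)
      dmin <- matrix(Inf, p$grid_rows, p$grid_cols)
      for (k in seq_len(p$n_urban_seeds))
        dmin <- pmin(dmin, sqrt((px - sx[k])^2 + (py - sy[k])^2))
    } else {
      dmin <- matrix(Inf, p$grid_rows, p$grid_cols)
    }
    # stable interior profile (identical every year)
    interior <- 63 - p$base_brightness_decay * pmax(dmin - p$core_radius, 0)
    interior[interior < p$fringe_dn] <- 0
    r_edge <- p$core_radius + (63 - p$fringe_dn) / p$base_brightness_decay
    stack <- vector("list", p$n_years)
    for (y in seq_len(p$n_years)) {
      r_lit <- r_edge * sqrt(1 + p$growth_rate)^(y - 1)
      dn <- interior
      dn[dn == 0 & dmin <= r_lit] <- p$fringe_dn  # expanding dim fringe
      dn <- round(pmin(pmax(dn, 0), 63))
      if (p$noise_sd > 0) {
        lit <- dn > 0
        dn[lit] <- round(pmin(pmax(dn[lit] + rnorm(sum(lit), 0, p$noise_sd),
                                   0), 63))
      }
      stack[[y]] <- composite_grid(dn, grid, p$start_year + y - 1L)
    }
    stack
  })
}

# ---- sensor distortion ------------------------------------------------------

#' Per-year second-order sensor distortion specification
#'
#' Each year's observed DN is `clamp(c0 + c1*DN + c2*DN^2 + noise, 0, 63)`;
#' truly dark pixels (DN = 0) are never distorted to positive values, matching
#' stable-lights semantics. At least one year must be the identity
#' `(0, 1, 0)` — the natural reference for intercalibration.
#'
#' @param c0,c1,c2 Numeric coefficient vectors, one element per year.
#' @param noise_sd Additive observation noise sd in DN (>= 0).
#' @return An object of class `distortion_spec`.
#' @export
distortion_spec <- function(c0, c1, c2, noise_sd = 0) {
  n <- length(c0)
  if (length(c1) != n || length(c2) != n || n < 1)
    stop("c0, c1, c2 must have equal positive length", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!any(c0 == 0 & c1 == 1 & c2 == 0))
    stop("distortion_spec must contain an identity year (0, 1, 0)",
         call. = FALSE)
  structure(list(c0 = as.numeric(c0), c1 = as.numeric(c1),
                 c2 = as.numeric(c2), noise_sd = noise_sd),
            class = "distortion_spec")
}

#' Draw a random near-identity distortion specification
#'
#' Coefficients per year: `c0 ~ U(-2, 2)`, `c1 ~ U(0.85, 1.15)`,
#' `c2 ~ U(-0.003, 0.001)`; the `identity_index` year (default: middle) is
#' forced to `(0, 1, 0)`.
#'
#' @param n_years Number of years.
#' @param identity_index Which year is undistorted.
#' @param noise_sd Observation noise sd in DN.
#' @param seed Integer seed.
#' @return A [distortion_spec()].
#' @export
random_distortion_spec <- function(n_years,
                                   identity_index = (n_years + 1) %/% 2,
                                   noise_sd = 1, seed = 1L) {
  with_seed(seed, {
    c0 <- runif(n_years, -2, 2)
    c1 <- runif(n_years, 0.85, 1.15)
    c2 <- runif(n_years, -0.003, 0.001)
    c0[identity_index] <- 0; c1[identity_index] <- 1; c2[identity_index] <- 0
    distortion_spec(c0, c1, c2, noise_sd)
  })
}

#' Apply one year's sensor distortion to a true composite
#'
#' @param truth A [composite_grid()] of true DN.
#' @param c0,c1,c2 Polynomial coefficients.
#' @param noise_sd Additive noise sd in DN (applied only where truth > 0).
#' @param seed Optional seed for the noise draw.
#' @return A [composite_grid()] of observed DN (fractional, clamped).
#' @export
apply_distortion <- function(truth, c0, c1, c2, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(truth, "composite_grid"))
  dn <- truth$dn
  obs <- c0 + c1 * dn + c2 * dn^2
  if (noise_sd > 0) {
    noise <- with_seed(seed, matrix(rnorm(length(dn), 0, noise_sd), nrow(dn)))
    obs <- obs + noise
  }
  obs <- pmin(pmax(obs, 0), 63)
  obs[dn == 0] <- 0  # no false lights
  composite_grid(obs, truth$grid, truth$year, truth$satellite)
}

#' Distort a whole stack year by year
#'
#' @param stack Year-ordered list of true [composite_grid()] objects.
#' @param spec A [distortion_spec()] with one coefficient triple per year.
#' @param seed Root seed; year `i` uses `seed + i`.
#' @return The observed stack.
#' @export
distort_stack <- function(stack, spec, seed = 1L) {
  stopifnot(inherits(spec, "distortion_spec"))
  if (length(spec$c0) != length(stack))
    stop("distortion_spec length does not match stack", call. = FALSE)
  lapply(seq_along(stack), function(i)
    apply_distortion(stack[[i]], spec$c0[i], spec$c1[i], spec$c2[i],
                     noise_sd = spec$noise_sd, seed = seed + i))
}

# ---- species ranges ---------------------------------------------------------

#' Parameters for the synthetic species-range generator
#'
#' Emulates a Global-Cactus-Assessment-style set of range maps: many species
#' with range sizes spanning single pixels to tens of thousands, spatially
#' clustered so that overlap produces a richness gradient, and per-species
#' flags for human use and threat status drawn at the assessment's observed
#' fractions (838/1,435 used; 417/1,435 threatened).
#'
#' @param n_species Number of species (default 1435).
#' @param range_size_min,range_size_max Range size bounds in pixels (drawn
#'   log-uniformly; defaults 1 and 10^4).
#' @param frac_used Expected fraction of species used by people.
#' @param frac_threatened Expected fraction with a threatened IUCN category.
#' @param n_hotspots Number of richness hotspots range centres cluster around.
#' @param hotspot_sd_frac Spatial sd of range centres around their hotspot,
#'   as a fraction of the smaller grid dimension.
#' @param hotspot_region Fractions `c(xmin, xmax, ymin, ymax)` of the grid in
#'   which hotspots sit. Hotspot x-positions are evenly spaced across this
#'   band (y random), so the richness gradient runs west-to-east by
#'   construction and its eastern tail meets the default light region:
#'   ranges reliably interface with light for any seed, while richness
#'   remains highest far from it.
#' @param seed Integer seed.
#' @return An object of class `range_params`.
#' @export
range_params <- function(n_species = 1435L, range_size_min = 1,
                         range_size_max = 1e4,
                         frac_used = 838 / 1435,
                         frac_threatened = 417 / 1435,
                         n_hotspots = 3L, hotspot_sd_frac = 0.08,
                         hotspot_region = c(0.1, 0.6, 0.1, 0.9),
                         seed = 1L) {
  if (frac_used < 0 || frac_used > 1 || frac_threatened < 0 ||
      frac_threatened > 1)
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (range_size_min < 1) stop("range_size_min must be >= 1", call. = FALSE)
  if (range_size_max < range_size_min)
    stop("range_size_max must be >= range_size_min", call. = FALSE)
  if (n_species < 1) stop("n_species must be >= 1", call. = FALSE)
  structure(list(n_species = as.integer(n_species),
                 range_size_min = range_size_min,
                 range_size_max = range_size_max,
                 frac_used = frac_used, frac_threatened = frac_threatened,
                 n_hotspots = as.integer(n_hotspots),
                 hotspot_sd_frac = hotspot_sd_frac,
                 hotspot_region = hotspot_region,
                 seed = as.integer(seed)),
            class = "range_params")
}

use_category_pool <- c("food (human)", "food (animal)", "medicine",
                       "ornamental", "construction", "fuel", "fences",
                       "cosmetics", "ritual", "other")

#' Generate synthetic species ranges with exact ground-truth masks
#'
#' Ranges are axis-aligned ellipses in pixel space, rasterized analytically by
#' the pixel-center rule, so ground-truth pixel membership is exact by
#' construction. A matching polygon geometry (96-gon) is attached so the set
#' also exercises the vector I/O and rasterization path. Every range has at
#' least one pixel (centre pixel fallback for sub-pixel ellipses).
#'
#' @param params A [range_params()].
#' @param grid A [grid_spec()] large enough to host the largest range.
#' @return An object of class `range_set`: lists `$ranges` ([species_range()])
#'   and `$masks` ([range_mask()]), plus `$grid` and `$params`.
#' @export
make_ranges <- function(params, grid) {
  stopifnot(inherits(params, "range_params"), inherits(grid, "grid_spec"))
  p <- params
  if (p$range_size_max > grid$rows * grid$cols)
    stop("range_size_max exceeds grid area", call. = FALSE)
  with_seed(p$seed, {
    hr <- p$hotspot_region
    # evenly spaced hotspot x: the light/richness interface exists for any seed
    hx <- (hr[1] + (hr[2] - hr[1]) *
             (seq_len(p$n_hotspots) - 0.5) / p$n_hotspots) * grid$cols
    hy <- runif(p$n_hotspots, hr[3] * grid$rows, hr[4] * grid$rows)
    sd_px <- p$hotspot_sd_frac * min(grid$rows, grid$cols)
    ranges <- vector("list", p$n_species)
    masks <- vector("list", p$n_species)
    for (i in seq_len(p$n_species)) {
      id <- sprintf("sp%04d", i)
      size <- exp(runif(1, log(p$range_size_min), log(p$range_size_max)))
      h <- sample.int(p$n_hotspots, 1)
      cx <- min(max(hx[h] + rnorm(1, 0, sd_px), 1), grid$cols - 1)
      cy <- min(max(hy[h] + rnorm(1, 0, sd_px), 1), grid$rows - 1)
      aspect <- exp(runif(1, -log(2), log(2)))
      a <- sqrt(size * aspect / pi)  # semi-axes in pixel units
      b <- sqrt(size / (aspect * pi))
      # analytic pixel-center membership: exact ground truth
      cols_c <- max(0, floor(cx - a - 1)):min(grid$cols - 1, ceiling(cx + a))
      rows_c <- max(0, floor(cy - b - 1)):min(grid$rows - 1, ceiling(cy + b))
      cand <- expand.grid(row = rows_c, col = cols_c)
      q <- ((cand$col + 0.5 - cx) / a)^2 + ((cand$row + 0.5 - cy) / b)^2
      inside <- q <= 1
      if (!any(inside)) {
        px <- cbind(row = floor(cy), col = floor(cx))
        q_in <- 0
      } else {
        px <- as.matrix(cand[inside, , drop = FALSE])
        q_in <- q[inside]
      }
      if (nrow(px) > p$range_size_max) {  # discretization overshoot guard
        keep <- order(q_in)[seq_len(p$range_size_max)]
        px <- px[keep, , drop = FALSE]
      }
      threatened <- runif(1) < p$frac_threatened
      category <- if (threatened) sample(c("CR", "EN", "VU"), 1)
                  else sample(c("LC", "NT"), 1, prob = c(0.8, 0.2))
      used <- runif(1) < p$frac_used
      uses <- if (used) sample(use_category_pool,
                               sample.int(3, 1)) else character()
      theta <- seq(0, 2 * pi, length.out = 97)[-97]
      ring <- cbind(grid$origin_x + (cx + a * cos(theta)) * grid$pixel_width,
                    grid$origin_y - (cy + b * sin(theta)) * grid$pixel_height)
      ranges[[i]] <- species_range(id, list(list(ring)),
                                   name = sprintf("Synthspecies %04d", i),
                                   category = category, used = used,
                                   use_categories = uses)
      masks[[i]] <- range_mask(id, px, grid)
    }
    structure(list(ranges = ranges, masks = masks, grid = grid, params = p),
              class = "range_set")
  })
}

#' @export
print.range_set <- function(x, ...) {
  np <- vapply(x$masks, `[[`, integer(1), "n_pixels")
  cat(sprintf("<range_set> %d species, range sizes %d-%d px, %d used, %d threatened\n",
              length(x$ranges), min(np), max(np),
              sum(vapply(x$ranges, `[[`, logical(1), "used")),
              sum(vapply(x$ranges, `[[`, logical(1), "threatened"))))
  invisible(x)
}

# ---- full bundle ------------------------------------------------------------

#' Generate a complete synthetic dataset with known ground truth
#'
#' Bundles a true nightscape stack, a distorted observed stack, a species
#' range set, and a per-species-per-year ground-truth exposure table computed
#' on the *true* (undistorted) stack — the yardstick for every downstream
#' stage.
#'
#' @param nightscape A [nightscape_params()].
#' @param distortion A [distortion_spec()] (or `NULL` for no distortion, in
#'   which case observed equals truth).
#' @param ranges A [range_params()].
#' @param threshold Darkness threshold in DN for the ground-truth table
#'   (default 5.5; lit means DN >= threshold).
#' @return An object of class `nightrange_bundle` with elements `truth`,
#'   `observed`, `ranges`, `truth_exposure`, `threshold` and `params`.
#' @export
make_dataset <- function(nightscape = nightscape_params(),
                         distortion = random_distortion_spec(
                           nightscape$n_years, seed = nightscape$seed + 1L),
                         ranges = range_params(seed = nightscape$seed + 2L),
                         threshold = 5.5) {
  truth <- make_nightscape(nightscape)
  grid <- truth[[1]]$grid
  observed <- if (is.null(distortion)) truth
              else distort_stack(truth, distortion, seed = nightscape$seed + 3L)
  rset <- make_ranges(ranges, grid)
  truth_exposure <- exposure_table(truth, rset$masks, threshold = threshold)
  structure(list(truth = truth, observed = observed, ranges = rset,
                 truth_exposure = truth_exposure, threshold = threshold,
                 params = list(nightscape = nightscape,
                               distortion = distortion, ranges = ranges)),
            class = "nightrange_bundle")
}

#' @export
print.nightrange_bundle <- function(x, ...) {
  cat(sprintf("<nightrange_bundle> %d years (%d-%d), %d x %d px, %d species\n",
              length(x$truth), x$truth[[1]]$year,
              x$truth[[length(x$truth)]]$year,
              x$truth[[1]]$grid$rows, x$truth[[1]]$grid$cols,
              length(x$ranges$ranges)))
  invisible(x)
}

#' Export a synthetic bundle to plain-text files
#'
#' Writes one ASCII grid per observed year (plus `truth/` subdirectory),
#' ranges as GeoJSON, the ground-truth exposure table as CSV, and a JSON
#' config block sufficient to regenerate the bundle.
#'
#' @param bundle A [make_dataset()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "nightrange_bundle"))
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  for (g in bundle$observed)
    write_asc(g, file.path(dir, sprintf("observed_%d.asc", g$year)))
  for (g in bundle$truth)
    write_asc(g, file.path(dir, "truth", sprintf("truth_%d.asc", g$year)))
  write_ranges(bundle$ranges$ranges, file.path(dir, "ranges.geojson"))
  utils::write.csv(bundle$truth_exposure,
                   file.path(dir, "truth_exposure.csv"), row.names = FALSE)
  cfg <- list(
    nightscape = unclass(bundle$params$nightscape),
    distortion = if (!is.null(bundle$params$distortion))
      unclass(bundle$params$distortion),
    ranges = unclass(bundle$params$ranges),
    threshold = bundle$threshold)
  jsonlite::write_json(cfg, file.path(dir, "bundle_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
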
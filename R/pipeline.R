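#' Configuration for a full pipeline run
#'
#' Either a synthetic bundle is generated (`synthetic = TRUE`, the default)
#' or rasters and ranges are read from disk. Periods are year vectors within
#' the stack span; they must not overlap.
#'
#' @param synthetic Generate a synthetic bundle instead of reading inputs?
#' @param raster_paths,raster_years,ranges_path File inputs (when
#'   `synthetic = FALSE`): one ASCII grid per year plus a GeoJSON of ranges.
#' @param nightscape,distortion,ranges Synthetic generator parameter objects
#'   (`NULL` means package defaults reseeded from `seed`).
#' @param reference_year Intercalibration reference (`NULL`: middle year).
#' @param threshold Darkness threshold in DN, in `(0, 63)`.
#' @param period_first,period_last Year vectors defining the two comparison
#'   periods (`NULL`: first five and last five stack years).
#' @param alpha Significance level for trend classification.
#' @param out_dir Output directory (`NULL`: nothing written).
#' @param seed Root integer seed; all synthetic randomness derives from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(synthetic = TRUE, raster_paths = NULL,
                       raster_years = NULL, ranges_path = NULL,
                       nightscape = NULL, distortion = NULL, ranges = NULL,
                       reference_year = NULL, threshold = 5.5,
                       period_first = NULL, period_last = NULL,
                       alpha = 0.05, out_dir = NULL, seed = 1L) {
  if (threshold <= 0 || threshold >= 63)
    stop("threshold must lie in (0, 63)", call. = FALSE)
  if (!is.null(period_first) && !is.null(period_last) &&
      length(intersect(period_first, period_last)))
    stop("periods must not overlap", call. = FALSE)
  structure(list(synthetic = synthetic, raster_paths = raster_paths,
                 raster_years = raster_years, ranges_path = ranges_path,
                 nightscape = nightscape, distortion = distortion,
                 ranges = ranges, reference_year = reference_year,
                 threshold = threshold, period_first = period_first,
                 period_last = period_last, alpha = alpha,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

resolve_synthetic <- function(config) {
  ns <- if (!is.null(config$nightscape)) config$nightscape
        else nightscape_params(seed = config$seed)
  dist <- if (!is.null(config$distortion)) config$distortion
          else random_distortion_spec(ns$n_years, seed = config$seed + 1L)
  rp <- if (!is.null(config$ranges)) config$ranges
        else range_params(seed = config$seed + 2L)
  make_dataset(ns, dist, rp, threshold = config$threshold)
}

#' Run the full ALAN-exposure analysis
#'
#' Stages: (1) acquire the observed stack and range masks (synthetic bundle
#' or files); (2) intercalibrate onto the reference year; (3) period-mean
#' images and per-species exposure per period and per year; (4) a Table-1
#' style category summary per scope; (5) Mann-Kendall trends per species and
#' on the across-species mean series; (6) 95%-cumulative-DN evenness per
#' period; (7) richness grids (all/threatened) and richness-brightness
#' correlations per period; (8) the used/not-used comparison. Each stage
#' failure aborts with the stage named.
#'
#' @param config A [run_config()].
#' @return An object of class `nightrange_results` (a named list of tables
#'   and model objects; see Details in the vignette). When
#'   `config$out_dir` is set, all tables plus a JSON manifest are written.
#' @export
nightrange_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    message("[nightrange] stage: ", name)
    tryCatch(force(expr),
             error = function(e) stop(sprintf("stage '%s' failed: %s",
                                              name, conditionMessage(e)),
                                      call. = FALSE))
  }

  acq <- stage("acquire", {
    if (config$synthetic) {
      bundle <- resolve_synthetic(config)
      list(stack = bundle$observed, rset = bundle$ranges, bundle = bundle)
    } else {
      stack <- read_stack(config$raster_paths, config$raster_years)
      rng <- load_ranges(config$ranges_path)
      grid <- stack[[1]]$grid
      masks <- lapply(rng, rasterize_range, grid = grid)
      list(stack = stack,
           rset = list(ranges = rng, masks = masks, grid = grid),
           bundle = NULL)
    }
  })
  stack <- acq$stack; rset <- acq$rset; bundle <- acq$bundle
  yrs <- stack_years(stack)
  masks <- rset$masks
  used <- vapply(rset$ranges, `[[`, logical(1), "used")
  threatened <- vapply(rset$ranges, `[[`, logical(1), "threatened")
  ids <- vapply(masks, `[[`, character(1), "species_id")

  cal <- stage("calibrate",
               calibrate_stack(stack, reference_year = config$reference_year,
                               fallback_identity = TRUE))
  cstack <- cal$stack

  p1 <- if (!is.null(config$period_first)) config$period_first
        else yrs[seq_len(min(5, length(yrs)))]
  p2 <- if (!is.null(config$period_last)) config$period_last
        else yrs[seq(length(yrs) - min(5, length(yrs)) + 1L, length(yrs))]
  lab1 <- sprintf("%d-%d", min(p1), max(p1))
  lab2 <- sprintf("%d-%d", min(p2), max(p2))

  expo <- stage("exposure", {
    mean1 <- period_mean(cstack, p1)
    mean2 <- period_mean(cstack, p2)
    per_period <- rbind(
      do.call(rbind, lapply(masks, function(m)
        range_exposure(mean1, m, config$threshold, scope = lab1))),
      do.call(rbind, lapply(masks, function(m)
        range_exposure(mean2, m, config$threshold, scope = lab2))))
    per_year <- exposure_table(cstack, masks, config$threshold)
    list(mean1 = mean1, mean2 = mean2, per_period = per_period,
         per_year = per_year)
  })

  table1 <- stage("table1", {
    scopes <- rbind(
      expo$per_year[expo$per_year$scope == as.character(min(yrs)), ],
      expo$per_year[expo$per_year$scope == as.character(max(yrs)), ],
      expo$per_period)
    do.call(rbind, lapply(split(scopes, scopes$scope), table1_analog))
  })

  trends <- stage("trends", {
    series <- lapply(masks, function(m)
      annual_lit_series(cstack, m, config$threshold))
    per_species <- lapply(seq_along(series), function(i)
      mann_kendall(series[[i]]$n_lit, series_id = ids[i]))
    global <- mann_kendall(mean_lit_series(series), series_id = "mean-all-species")
    list(per_species = trend_table(per_species),
         counts = classify_trends(per_species, alpha = config$alpha),
         global = global)
  })

  evenness <- stage("evenness", {
    ev <- rbind(
      do.call(rbind, lapply(masks, function(m)
        evenness_95(expo$mean1, m, scope = lab1))),
      do.call(rbind, lapply(masks, function(m)
        evenness_95(expo$mean2, m, scope = lab2))))
    e1 <- ev$frac_pixels_for_95[ev$scope == lab1]
    e2 <- ev$frac_pixels_for_95[ev$scope == lab2]
    both <- !is.na(e1) & !is.na(e2)
    list(table = ev,
         frac_species_spread_increased =
           if (any(both)) mean(e2[both] > e1[both]) else NA_real_)
  })

  rich <- stage("richness", {
    grid <- stack[[1]]$grid
    all_grid <- build_richness(masks, grid, "all")
    thr_grid <- build_richness(masks, grid, "threatened",
                               threatened = threatened)
    cors <- list()
    for (sub in c("all", "threatened")) {
      rg <- if (sub == "all") all_grid else thr_grid
      if (max(rg$counts) == 0) next
      for (per in c(lab1, lab2)) {
        img <- if (per == lab1) expo$mean1 else expo$mean2
        cors[[paste(sub, per, sep = "|")]] <- tryCatch(
          richness_brightness_cor(rg, img),
          error = function(e) structure(
            list(r = NA_real_, n = NA_integer_, ci_low = NA_real_,
                 ci_high = NA_real_, p_two_sided = NA_real_,
                 defined = FALSE), class = "correlation_result"))
      }
    }
    list(all = all_grid, threatened = thr_grid, correlations = cors,
         levels_last = richness_levels(all_grid, expo$mean2),
         classes = bin_richness(all_grid))
  })

  use_cmp <- stage("group_comparison", {
    if (sum(used) >= 2 && sum(!used) >= 2) {
      pp <- expo$per_period
      prop1 <- pp$prop_lit[pp$scope == lab1]
      prop2 <- pp$prop_lit[pp$scope == lab2]
      avg <- (prop1 + prop2) / 2
      list(first = compare_use(prop1[used], prop1[!used]),
           last = compare_use(prop2[used], prop2[!used]),
           both = compare_use(avg[used], avg[!used]))
    } else NULL
  })

  res <- structure(list(
    config = config, bundle = bundle, years = yrs,
    periods = list(first = p1, last = p2),
    calibration = cal$model,
    exposure_per_period = expo$per_period,
    exposure_per_year = expo$per_year,
    table1_analog = table1,
    summary_percentages = lapply(
      split(expo$per_year, expo$per_year$scope), summarize_percentages),
    trends = trends, evenness = evenness, richness = rich,
    use_comparison = use_cmp), class = "nightrange_results")
  if (!is.null(config$out_dir)) stage("write", write_results(res))
  res
}

#' Table-1 style category summary for one scope
#'
#' Partitions species into "with lit pixels", "with no lit pixels" and "with
#' only lit pixels" (the last is a subset of the first) and reports counts
#' and range-size spans.
#'
#' @param exposure One-scope slice of an exposure table (one row per species).
#' @return Data frame `(scope, category, n_species, range_min, range_max)`.
#' @export
table1_analog <- function(exposure) {
  if (!nrow(exposure)) stop("empty exposure table", call. = FALSE)
  grp <- list(
    "With lit pixels in their range" = exposure$n_lit > 0,
    "With no lit pixels in their range" = exposure$n_lit == 0,
    "With only lit pixels in their range" =
      exposure$n_lit == exposure$n_pixels)
  do.call(rbind, lapply(names(grp), function(g) {
    sel <- grp[[g]]
    data.frame(scope = exposure$scope[1], category = g,
               n_species = sum(sel),
               range_min = if (any(sel)) min(exposure$n_pixels[sel]) else NA,
               range_max = if (any(sel)) max(exposure$n_pixels[sel]) else NA,
               stringsAsFactors = FALSE)
  }))
}

#' Percentages of species by lit-range category
#'
#' @param exposure One-scope slice of an exposure table (one row per species).
#' @return Named list `pct_with_lit`, `pct_all_lit`, `pct_dark` (percentages
#'   of the analysed species set; the three categories' counts partition it,
#'   with "all lit" a subset of "with lit").
#' @export
summarize_percentages <- function(exposure) {
  n <- nrow(exposure)
  if (!n) stop("empty exposure table", call. = FALSE)
  list(pct_with_lit = 100 * sum(exposure$n_lit > 0) / n,
       pct_all_lit = 100 * sum(exposure$n_lit == exposure$n_pixels) / n,
       pct_dark = 100 * sum(exposure$n_lit == 0) / n)
}

#' @export
print.nightrange_results <- function(x, ...) {
  cat("<nightrange_results>\n")
  cat(sprintf("  years %d-%d, %d species\n", min(x$years), max(x$years),
              length(unique(x$exposure_per_year$species_id))))
  for (sc in names(x$summary_percentages)) {
    s <- x$summary_percentages[[sc]]
    cat(sprintf("  %s: %.1f%% with lit pixels, %.1f%% fully lit, %.1f%% dark\n",
                sc, s$pct_with_lit, s$pct_all_lit, s$pct_dark))
  }
  g <- x$trends$global
  cat(sprintf("  global trend: tau = %.2f, p = %.3g; per-species +%d/-%d/none %d\n",
              g$tau, g$p_two_sided, x$trends$counts["positive"],
              x$trends$counts["negative"], x$trends$counts["none"]))
  cat(sprintf("  spread increased for %.1f%% of species\n",
              100 * x$evenness$frac_species_spread_increased))
  for (nm in names(x$richness$correlations)) {
    r <- x$richness$correlations[[nm]]
    cat(sprintf("  richness-brightness %s: r = %.3f (%.3f, %.3f)\n",
                nm, r$r, r$ci_low, r$ci_high))
  }
  if (!is.null(x$use_comparison)) {
    u <- x$use_comparison$last
    cat(sprintf("  use comparison (last period): F(%d,%d) = %.2f, p = %.3g\n",
                u$df_between, u$df_within, u$F, u$p_two_sided))
  }
  invisible(x)
}

write_results <- function(res) {
  dir.create(res$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- res$config$out_dir
  utils::write.csv(res$exposure_per_period,
                   file.path(od, "exposure_per_period.csv"), row.names = FALSE)
  utils::write.csv(res$exposure_per_year,
                   file.path(od, "exposure_per_year.csv"), row.names = FALSE)
  utils::write.csv(res$table1_analog, file.path(od, "table1_analog.csv"),
                   row.names = FALSE)
  utils::write.csv(res$trends$per_species,
                   file.path(od, "trends_per_species.csv"), row.names = FALSE)
  utils::write.csv(res$evenness$table, file.path(od, "evenness.csv"),
                   row.names = FALSE)
  utils::write.csv(res$richness$levels_last,
                   file.path(od, "richness_levels.csv"), row.names = FALSE)
  write_calibration_json(res$calibration, file.path(od, "calibration.json"))
  cors <- lapply(res$richness$correlations, function(r)
    r[c("r", "n", "ci_low", "ci_high", "p_two_sided", "defined")])
  g <- res$trends$global
  manifest <- list(
    package_version = as.character(utils::packageVersion("nightrange")),
    seed = res$config$seed, threshold = res$config$threshold,
    alpha = res$config$alpha,
    periods = res$periods, years = res$years,
    summary_percentages = res$summary_percentages,
    global_trend = list(S = g$S, tau = g$tau, p = g$p_two_sided),
    trend_counts = as.list(res$trends$counts),
    frac_species_spread_increased =
      res$evenness$frac_species_spread_increased,
    richness_correlations = cors,
    use_comparison = if (!is.null(res$use_comparison)) lapply(
      res$use_comparison, function(u)
        u[c("F", "df_between", "df_within", "p_two_sided",
            "ci_low", "ci_high")]))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(od)
}

#' Load a pipeline configuration from JSON
#'
#' Recognized top-level keys mirror [run_config()] arguments; nested
#' `nightscape`, `distortion` and `ranges` objects are passed to their
#' parameter constructors.
#'
#' @param path JSON file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  ns <- if (!is.null(cfg$nightscape))
    do.call(nightscape_params, cfg$nightscape)
  dist <- if (!is.null(cfg$distortion))
    do.call(distortion_spec, cfg$distortion)
  rp <- if (!is.null(cfg$ranges)) do.call(range_params, cfg$ranges)
  run_config(
    synthetic = if (!is.null(cfg$synthetic)) cfg$synthetic
                else is.null(cfg$raster_paths),
    raster_paths = cfg$raster_paths, raster_years = cfg$raster_years,
    ranges_path = cfg$ranges_path,
    nightscape = ns, distortion = dist, ranges = rp,
    reference_year = cfg$reference_year,
    threshold = if (!is.null(cfg$threshold)) cfg$threshold else 5.5,
    period_first = cfg$period_first, period_last = cfg$period_last,
    alpha = if (!is.null(cfg$alpha)) cfg$alpha else 0.05,
    out_dir = cfg$out_dir,
    seed = if (!is.null(cfg$seed)) cfg$seed else 1L)
}
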
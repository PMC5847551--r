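#' Classify DN values as lit or dark
#'
#' Darkness is DN strictly below the threshold: a pixel at exactly 5.5 DN is
#' lit. The default 5.5 is twice the detection limit for DN change, a
#' conservative bound on detectable artificial light.
#'
#' @param dn Numeric DN values in `[0, 63]`.
#' @param threshold Darkness threshold in DN (default 5.5).
#' @return Logical vector: `TRUE` where lit (`dn >= threshold`).
#' @export
classify_lit <- function(dn, threshold = 5.5) dn >= threshold

#' Per-pixel mean composite over a set of years
#'
#' Arithmetic mean of calibrated DN; `NA` (nodata) at any member year
#' propagates to the mean. The result carries the first requested year as its
#' nominal year and a period label as its satellite field.
#'
#' @param stack Year-ordered list of [composite_grid()] objects.
#' @param years Calendar years to average (all must be present).
#' @return A [composite_grid()] of mean DN.
#' @export
period_mean <- function(stack, years) {
  yrs <- check_stack(stack)
  miss <- setdiff(years, yrs)
  if (length(miss))
    stop("years missing from stack: ", paste(miss, collapse = ", "),
         call. = FALSE)
  sel <- stack[match(years, yrs)]
  acc <- sel[[1]]$dn
  for (g in sel[-1]) acc <- acc + g$dn
  composite_grid(acc / length(sel), sel[[1]]$grid, min(years),
                 satellite = sprintf("%d-%d", min(years), max(years)))
}

#' ALAN exposure of one species range on one composite
#'
#' @param grid A [composite_grid()] (typically calibrated or a period mean).
#' @param mask A [range_mask()] on the same grid.
#' @param threshold Darkness threshold in DN.
#' @param scope Label for the record's scope (year or period), defaults to
#'   the composite's year.
#' @return One-row data frame: `species_id`, `scope`, `n_pixels`, `n_lit`,
#'   `prop_lit`, `pct_range_lit`, `mean_dn`, `sum_dn`.
#' @export
range_exposure <- function(grid, mask, threshold = 5.5,
                           scope = as.character(grid$year)) {
  stopifnot(inherits(grid, "composite_grid"), inherits(mask, "range_mask"))
  check_same_grid(grid$grid, mask$grid, "composite and mask")
  vals <- grid$dn[mask$idx]
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    stop("mask covers only nodata pixels for species ", mask$species_id,
         call. = FALSE)
  n <- length(vals)
  n_lit <- sum(classify_lit(vals, threshold))
  data.frame(species_id = mask$species_id, scope = scope,
             n_pixels = n, n_lit = n_lit, prop_lit = n_lit / n,
             pct_range_lit = 100 * n_lit / n,
             mean_dn = mean(vals), sum_dn = sum(vals),
             stringsAsFactors = FALSE)
}

#' Annual lit-pixel counts for one species
#'
#' @param stack Year-ordered calibrated stack.
#' @param mask A [range_mask()].
#' @param threshold Darkness threshold in DN.
#' @return Data frame of `(year, n_lit)` in year order.
#' @export
annual_lit_series <- function(stack, mask, threshold = 5.5) {
  yrs <- check_stack(stack)
  check_same_grid(stack[[1]]$grid, mask$grid, "stack and mask")
  n_lit <- vapply(stack, function(g)
    sum(classify_lit(g$dn[mask$idx], threshold), na.rm = TRUE), numeric(1))
  data.frame(year = yrs, n_lit = n_lit)
}

#' Exposure table for many species across a stack
#'
#' One row per species x year; the workhorse behind both the ground-truth
#' table of synthetic bundles and the pipeline's per-year output.
#'
#' @param stack Year-ordered stack.
#' @param masks List of [range_mask()] objects.
#' @param threshold Darkness threshold in DN.
#' @return Data frame with [range_exposure()] columns.
#' @export
exposure_table <- function(stack, masks, threshold = 5.5) {
  yrs <- check_stack(stack)
  if (!length(masks)) return(empty_exposure_table())
  for (m in masks) check_same_grid(stack[[1]]$grid, m$grid, "stack and mask")
  ns <- length(masks); ny <- length(stack)
  n <- ns * ny
  sid <- character(n); scope <- character(n)
  n_px <- integer(n); n_lit <- integer(n)
  mean_dn <- numeric(n); sum_dn <- numeric(n)
  k <- 0L
  for (m in masks) {
    for (i in seq_len(ny)) {
      k <- k + 1L
      vals <- stack[[i]]$dn[m$idx]
      vals <- vals[!is.na(vals)]
      sid[k] <- m$species_id
      scope[k] <- as.character(yrs[i])
      n_px[k] <- length(vals)
      n_lit[k] <- sum(vals >= threshold)
      mean_dn[k] <- mean(vals)
      sum_dn[k] <- sum(vals)
    }
  }
  data.frame(species_id = sid, scope = scope, n_pixels = n_px, n_lit = n_lit,
             prop_lit = n_lit / n_px, pct_range_lit = 100 * n_lit / n_px,
             mean_dn = mean_dn, sum_dn = sum_dn, stringsAsFactors = FALSE)
}

empty_exposure_table <- function() {
  data.frame(species_id = character(), scope = character(),
             n_pixels = integer(), n_lit = integer(), prop_lit = numeric(),
             pct_range_lit = numeric(), mean_dn = numeric(),
             sum_dn = numeric(), stringsAsFactors = FALSE)
}

#' Fraction of range pixels contributing 95% of cumulative brightness
#'
#' Sorts the range's DN values in descending order and finds the smallest
#' pixel count `k` whose cumulative sum reaches 95% of the range's total DN;
#' the statistic is `k / n_pixels`. Small values mean light concentrated in
#' few pixels; a uniformly lit range approaches `ceiling(0.95 n) / n`. For a
#' fully dark range (total DN 0) the statistic is undefined.
#'
#' @param grid A [composite_grid()].
#' @param mask A [range_mask()] on the same grid.
#' @param quantile Cumulative-brightness fraction (default 0.95).
#' @param scope Scope label, defaults to the composite's year.
#' @return One-row data frame: `species_id`, `scope`, `frac_pixels_for_95`
#'   (`NA` when undefined), `defined`.
#' @export
evenness_95 <- function(grid, mask, quantile = 0.95,
                        scope = as.character(grid$year)) {
  stopifnot(inherits(grid, "composite_grid"), inherits(mask, "range_mask"))
  check_same_grid(grid$grid, mask$grid, "composite and mask")
  vals <- grid$dn[mask$idx]
  vals <- vals[!is.na(vals)]
  tot <- sum(vals)
  if (!length(vals) || tot <= 0)
    return(data.frame(species_id = mask$species_id, scope = scope,
                      frac_pixels_for_95 = NA_real_, defined = FALSE,
                      stringsAsFactors = FALSE))
  cs <- cumsum(sort(vals, decreasing = TRUE))
  k <- which(cs >= quantile * tot)[1]
  data.frame(species_id = mask$species_id, scope = scope,
             frac_pixels_for_95 = k / length(vals), defined = TRUE,
             stringsAsFactors = FALSE)
}

#' All-years average range DN per species
#'
#' The mean over years of the per-year range-mean DN — a smoother exposure
#' measure than any single year.
#'
#' @param stack Year-ordered calibrated stack.
#' @param mask A [range_mask()].
#' @return Numeric scalar.
#' @export
mean_dn_all_years <- function(stack, mask) {
  check_stack(stack)
  mean(vapply(stack, function(g) mean(g$dn[mask$idx], na.rm = TRUE),
              numeric(1)))
}
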
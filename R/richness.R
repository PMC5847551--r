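#' Build a species-richness grid from range masks
#'
#' Each pixel counts the species whose rasterized range contains it. The sum
#' over the grid equals the sum of per-species pixel counts exactly
#' (conservation), so the grid is an exact overlay, not an approximation.
#'
#' @param masks List of [range_mask()] objects on a common grid.
#' @param grid The common [grid_spec()].
#' @param subset `"all"` (default) or `"threatened"`; when `"threatened"`,
#'   supply `threatened` flags.
#' @param threatened Logical vector aligned with `masks` (required for the
#'   threatened subset).
#' @return An object of class `richness_grid`: integer `counts` matrix,
#'   `subset` label, `grid`.
#' @export
build_richness <- function(masks, grid, subset = c("all", "threatened"),
                           threatened = NULL) {
  subset <- match.arg(subset)
  stopifnot(inherits(grid, "grid_spec"))
  keep <- masks
  if (subset == "threatened") {
    if (is.null(threatened) || length(threatened) != length(masks))
      stop("threatened flags required for the threatened subset",
           call. = FALSE)
    keep <- masks[threatened]
  }
  counts <- matrix(0L, grid$rows, grid$cols)
  for (m in keep) {
    check_same_grid(grid, m$grid, "richness grid and mask")
    counts[m$idx] <- counts[m$idx] + 1L
  }
  structure(list(counts = counts, subset = subset, grid = grid),
            class = "richness_grid")
}

#' @export
print.richness_grid <- function(x, ...) {
  cat(sprintf("<richness_grid> subset=%s, max richness %d, %d occupied pixels\n",
              x$subset, max(x$counts), sum(x$counts > 0)))
  invisible(x)
}

#' Summarize brightness by richness level
#'
#' Treats each occupied richness level as a mask on a composite (typically
#' the last-period mean image) and reports pixel count and mean DN per level.
#' Levels with no pixels are omitted.
#'
#' @param richness A `richness_grid`.
#' @param dn A [composite_grid()] on the same grid.
#' @return Data frame `(richness, n_pixels, mean_dn)`, one row per occupied
#'   level `k >= 1`.
#' @export
richness_levels <- function(richness, dn) {
  stopifnot(inherits(richness, "richness_grid"),
            inherits(dn, "composite_grid"))
  check_same_grid(richness$grid, dn$grid, "richness and composite")
  occ <- richness$counts > 0 & !is.na(dn$dn)
  if (!any(occ)) stop("richness grid has no occupied pixels", call. = FALSE)
  lev <- richness$counts[occ]
  vals <- dn$dn[occ]
  agg <- tapply(vals, lev, function(v) c(n = length(v), mean = mean(v)))
  k <- as.integer(names(agg))
  out <- data.frame(richness = k,
                    n_pixels = vapply(agg, `[[`, numeric(1), "n"),
                    mean_dn = vapply(agg, `[[`, numeric(1), "mean"))
  out[order(out$richness), , drop = FALSE]
}

#' Bin richness into equal-width classes
#'
#' Integer intervals of width `ceiling(max_richness / n_classes)` starting at
#' 1 (e.g. max 82 in 5 classes gives 1-17, 18-34, ...); zero-richness pixels
#' stay unclassed (`NA`).
#'
#' @param richness A `richness_grid`.
#' @param n_classes Number of classes (default 5).
#' @return List with `class_map` (integer matrix, `NA` where richness 0) and
#'   `intervals` (data frame `class`, `from`, `to`).
#' @export
bin_richness <- function(richness, n_classes = 5L) {
  stopifnot(inherits(richness, "richness_grid"))
  mx <- max(richness$counts)
  if (mx < 1) stop("all-zero richness grid cannot be binned", call. = FALSE)
  if (mx < n_classes) n_classes <- mx
  w <- ceiling(mx / n_classes)
  cls <- (richness$counts - 1L) %/% w + 1L
  cls[richness$counts == 0L] <- NA_integer_
  intervals <- data.frame(class = seq_len(n_classes),
                          from = (seq_len(n_classes) - 1L) * w + 1L,
                          to = pmin(seq_len(n_classes) * w, mx))
  list(class_map = cls, intervals = intervals)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' `r` by the product-moment formula, a 95% CI from the Fisher z transform
#' (`atanh(r) +/- 1.96/sqrt(n-3)`), and a two-sided p-value from
#' `t = r * sqrt((n-2)/(1-r^2))`. A constant input yields an undefined
#' (flagged) result rather than an error.
#'
#' @param x,y Numeric vectors, length >= 4.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `correlation_result`: `r`, `n`, `ci_low`,
#'   `ci_high`, `p_two_sided`, `defined`.
#' @export
pearson_with_ci <- function(x, y, conf = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need n >= 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(list(r = NA_real_, n = n, ci_low = NA_real_,
                          ci_high = NA_real_, p_two_sided = NA_real_,
                          defined = FALSE),
                     class = "correlation_result"))
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  ci <- tanh(z + c(-1, 1) * zc / sqrt(n - 3))
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(list(r = r, n = n, ci_low = ci[1], ci_high = ci[2],
                 p_two_sided = p, defined = TRUE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (!x$defined) cat("<correlation_result> undefined (constant input)\n")
  else cat(sprintf("<correlation_result> r=%.3f (95%% CI %.3f to %.3f), n=%d, p=%.4g\n",
                   x$r, x$ci_low, x$ci_high, x$n, x$p_two_sided))
  invisible(x)
}

#' Richness-brightness correlation
#'
#' The headline unit is one point per occupied richness level (mean DN per
#' level); `per_pixel = TRUE` instead correlates richness with DN across all
#' occupied pixels, a variant with much larger n.
#'
#' @param richness A `richness_grid`.
#' @param dn A [composite_grid()] (typically a period-mean image).
#' @param per_pixel Correlation unit: richness levels (default) or pixels.
#' @return A `correlation_result`.
#' @export
richness_brightness_cor <- function(richness, dn, per_pixel = FALSE) {
  if (per_pixel) {
    check_same_grid(richness$grid, dn$grid, "richness and composite")
    occ <- richness$counts > 0 & !is.na(dn$dn)
    pearson_with_ci(as.numeric(richness$counts[occ]), dn$dn[occ])
  } else {
    lv <- richness_levels(richness, dn)
    pearson_with_ci(lv$richness, lv$mean_dn)
  }
}
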
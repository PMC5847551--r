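#' Arcsine square root transform of a proportion
#'
#' `asin(sqrt(p))` in radians, mapping `[0, 1]` onto `[0, pi/2]` — the
#' classical variance-stabilizing transform for proportions ahead of linear
#' modelling. Values outside `[0, 1]` by at most `1e-9` (floating-point
#' slop) are clamped; anything further out is a domain error.
#'
#' @param p Proportions in `[0, 1]`.
#' @return Transformed values in `[0, pi/2]`.
#' @export
arcsine_sqrt <- function(p) {
  if (any(p < -1e-9 | p > 1 + 1e-9, na.rm = TRUE))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  asin(sqrt(pmin(pmax(p, 0), 1)))
}

#' Compare lit-range proportions between used and unused species
#'
#' One-way, two-group ANOVA (a general linear model with a single fixed
#' factor) on arcsine-square-root transformed lit proportions. Equivalent to
#' the pooled-variance two-sample t-test: `F = t^2` with
#' `df = (1, n_total - 2)`. The 95% CI of the group-mean difference
#' (used minus not used) is on the transformed scale; raw-scale group means
#' are reported alongside.
#'
#' @param values_used,values_not_used Lit proportions (in `[0, 1]`) for
#'   species used / not used by people; each group needs >= 2 members.
#' @param transform Apply [arcsine_sqrt()] first (default `TRUE`).
#' @return An object of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p_two_sided`, `diff` (transformed scale), `ci_low`, `ci_high`,
#'   `n_used`, `n_not_used`, `mean_used`, `mean_not_used` (transformed),
#'   `raw_mean_used`, `raw_mean_not_used`.
#' @export
compare_use <- function(values_used, values_not_used, transform = TRUE) {
  if (length(values_used) < 2 || length(values_not_used) < 2)
    stop("each group needs >= 2 members", call. = FALSE)
  raw_u <- values_used; raw_n <- values_not_used
  if (transform) {
    values_used <- arcsine_sqrt(values_used)
    values_not_used <- arcsine_sqrt(values_not_used)
  }
  n1 <- length(values_used); n2 <- length(values_not_used)
  m1 <- mean(values_used); m2 <- mean(values_not_used)
  df_w <- n1 + n2 - 2L
  sp2 <- (sum((values_used - m1)^2) + sum((values_not_used - m2)^2)) / df_w
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- if (se > 0) (m1 - m2) / se else 0
  Fstat <- tstat^2
  p <- if (se > 0) 2 * stats::pt(-abs(tstat), df = df_w) else 1
  tcrit <- stats::qt(0.975, df = df_w)
  structure(list(F = Fstat, df_between = 1L, df_within = df_w,
                 p_two_sided = p, diff = m1 - m2,
                 ci_low = m1 - m2 - tcrit * se,
                 ci_high = m1 - m2 + tcrit * se,
                 n_used = n1, n_not_used = n2,
                 mean_used = m1, mean_not_used = m2,
                 raw_mean_used = mean(raw_u),
                 raw_mean_not_used = mean(raw_n)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d,%d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p_two_sided))
  cat(sprintf("  diff (transformed) = %.4f, 95%% CI %.4f to %.4f\n",
              x$diff, x$ci_low, x$ci_high))
  cat(sprintf("  used: n=%d mean=%.4f (raw %.4f); not used: n=%d mean=%.4f (raw %.4f)\n",
              x$n_used, x$mean_used, x$raw_mean_used,
              x$n_not_used, x$mean_not_used, x$raw_mean_not_used))
  invisible(x)
}
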
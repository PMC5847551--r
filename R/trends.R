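#' Mann-Kendall test for monotonic trend
#'
#' Computed from first principles: `S = sum_{i<j} sign(x_j - x_i)`; the
#' variance of `S` under the null carries the standard correction for tied
#' groups, `var_S = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18`; tau is the
#' tie-adjusted tau-b; the normal deviate uses the continuity correction
#' (`z = (S - sign(S)) / sqrt(var_S)`, 0 when `S = 0`). A constant series is
#' not an error: it returns `tau = 0`, `p = 1`.
#'
#' For short tie-free series (`n <= 10`) `exact = TRUE` replaces the normal
#' approximation with the exact permutation null distribution of `S`,
#' enumerated through the inversion-count generating function
#' `prod_k (1 + x + ... + x^(k-1))`. With ties the exact option falls back to
#' the normal approximation with a warning.
#'
#' @param series Numeric vector in time order, length >= 3.
#' @param series_id Optional label carried into the result.
#' @param exact Logical: exact small-sample p-value (tie-free, `n <= 10`).
#' @return An object of class `trend_result` with fields `series_id`, `n`,
#'   `S`, `var_S`, `tau`, `z`, `p_two_sided`.
#' @export
mann_kendall <- function(series, series_id = NA_character_, exact = FALSE) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 3 || anyNA(x))
    stop("mann_kendall needs a complete series of length >= 3", call. = FALSE)
  d <- sign(outer(x, x, "-"))
  S <- sum(d[lower.tri(d)])  # lower.tri: rows i > cols j, i.e. x_later - x_earlier
  ties <- table(x)
  ties <- ties[ties > 1]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  n0 <- n * (n - 1) / 2
  n1 <- sum(ties * (ties - 1) / 2)  # tie correction for x; time axis has none
  denom <- sqrt((n0 - n1) * n0)
  tau <- if (denom > 0) S / denom else 0
  if (var_S > 0) {
    z <- if (S > 0) (S - 1) / sqrt(var_S)
         else if (S < 0) (S + 1) / sqrt(var_S) else 0
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    z <- 0; p <- 1
  }
  if (exact) {
    if (length(unique(x)) == n && n <= 10) {
      p <- mk_exact_p(S, n)
    } else {
      warning("exact p-value requires a tie-free series with n <= 10; using normal approximation",
              call. = FALSE)
    }
  }
  structure(list(series_id = series_id, n = n, S = S, var_S = var_S,
                 tau = tau, z = z, p_two_sided = min(p, 1)),
            class = "trend_result")
}

# Exact two-sided P(|S| >= |s|) for tie-free series: the inversion-count
# distribution is prod_{k=1}^{n} (1 + x + ... + x^{k-1}); S = n(n-1)/2 - 2*inv.
mk_exact_p <- function(s, n) {
  counts <- 1
  for (k in 2:n) {
    new <- numeric(length(counts) + k - 1)
    for (shift in 0:(k - 1))
      new[seq_along(counts) + shift] <- new[seq_along(counts) + shift] + counts
    counts <- new
  }
  n0 <- n * (n - 1) / 2
  S_vals <- n0 - 2 * (seq_along(counts) - 1)
  sum(counts[abs(S_vals) >= abs(s)]) / sum(counts)
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> %s: n=%d S=%d tau=%.3f z=%.3f p=%.4g\n",
              x$series_id, x$n, x$S, x$tau, x$z, x$p_two_sided))
  invisible(x)
}

#' Across-species mean lit-pixel series
#'
#' @param series_list List of equal-length numeric vectors (or data frames
#'   from [annual_lit_series()]), all sharing the same year axis.
#' @return Numeric vector of per-year means.
#' @export
mean_lit_series <- function(series_list) {
  if (!length(series_list)) stop("empty series collection", call. = FALSE)
  vecs <- lapply(series_list, function(s)
    if (is.data.frame(s)) s$n_lit else as.numeric(s))
  lens <- lengths(vecs)
  if (length(unique(lens)) != 1)
    stop("all series must share the year axis", call. = FALSE)
  colMeans(do.call(rbind, vecs))
}

#' Classify per-species trend results at a significance level
#'
#' @param results List of `trend_result` objects.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Named integer vector `c(positive, negative, none)`; positive means
#'   `tau > 0 & p < alpha`, negative `tau < 0 & p < alpha`.
#' @export
classify_trends <- function(results, alpha = 0.05) {
  if (!length(results)) stop("empty results collection", call. = FALSE)
  tau <- vapply(results, `[[`, numeric(1), "tau")
  p <- vapply(results, `[[`, numeric(1), "p_two_sided")
  pos <- sum(tau > 0 & p < alpha)
  neg <- sum(tau < 0 & p < alpha)
  c(positive = pos, negative = neg, none = length(results) - pos - neg)
}

#' Trend results as a tidy data frame
#'
#' @param results List of `trend_result` objects.
#' @param bh Logical: append Benjamini-Hochberg adjusted q-values (the core
#'   analysis applies no multiple-testing correction; this is opt-in).
#' @return Data frame of trend-result fields.
#' @export
trend_table <- function(results, bh = FALSE) {
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(series_id = r$series_id, n = r$n, S = r$S, var_S = r$var_S,
               tau = r$tau, z = r$z, p_two_sided = r$p_two_sided,
               stringsAsFactors = FALSE)))
  if (bh) df$q_bh <- stats::p.adjust(df$p_two_sided, method = "BH")
  df
}
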
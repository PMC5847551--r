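#' Select stable pixels for intercalibration
#'
#' Truly change-free areas are hard to delimit, so the default "stable" set is
#' simply all pixels lit in both the reference and the target year; the
#' robust median fit downstream absorbs genuinely changed pixels. Optional
#' MAD trimming iteratively refits and drops pixels whose absolute residual
#' exceeds `k` times the median absolute deviation, up to `max_iter` rounds.
#'
#' @param reference,target [composite_grid()] objects on the same grid.
#' @param trim Logical: apply iterative MAD trimming?
#' @param k MAD multiplier for trimming (default 3).
#' @param max_iter Maximum trimming iterations (default 5).
#' @return Integer vector of 1-based linear pixel indices.
#' @export
select_stable_pixels <- function(reference, target, trim = FALSE, k = 3,
                                 max_iter = 5L) {
  check_same_grid(reference$grid, target$grid, "reference and target")
  idx <- which(reference$dn > 0 & target$dn > 0 &
                 !is.na(reference$dn) & !is.na(target$dn))
  if (length(idx) < 30)
    stop("insufficient data: fewer than 30 co-lit pixels for calibration",
         call. = FALSE)
  if (trim) {
    for (it in seq_len(max_iter)) {
      cf <- fit_calibration(reference$dn[idx], target$dn[idx])
      r <- reference$dn[idx] -
        (cf[1] + cf[2] * target$dn[idx] + cf[3] * target$dn[idx]^2)
      m <- stats::mad(r, center = 0)
      if (m == 0) break
      keep <- abs(r) <= k * m
      if (all(keep) || sum(keep) < 30) break
      idx <- idx[keep]
    }
  }
  idx
}

#' Fit a second-order calibration curve by median (L1) regression
#'
#' Fits `reference = c0 + c1*target + c2*target^2` minimizing the sum of
#' absolute residuals — quantile regression through the median, insensitive
#' to the outlying values that distort an ordinary least-squares quadratic.
#' Solved by iteratively reweighted least squares with epsilon-smoothed
#' weights; iteration stops when the L1 objective improves by less than
#' 1e-8 (relative), well inside the 1e-6 contract. Deterministic for fixed
#' input.
#'
#' @param reference_dn,target_dn Paired DN vectors, length >= 30.
#' @return Named numeric vector `c(c0, c1, c2)`.
#' @export
fit_calibration <- function(reference_dn, target_dn) {
  y <- as.numeric(reference_dn); t <- as.numeric(target_dn)
  if (length(y) != length(t) || length(y) < 30)
    stop("need >= 30 paired DN values", call. = FALSE)
  if (length(unique(t)) < 2)
    stop("degenerate design: all target DN values equal", call. = FALSE)
  X <- cbind(1, t, t^2)
  beta <- stats::lm.fit(X, y)$coefficients
  beta[is.na(beta)] <- 0
  obj <- sum(abs(y - X %*% beta))
  eps <- 1e-6
  for (it in seq_len(200L)) {
    r <- as.numeric(y - X %*% beta)
    w <- 1 / pmax(abs(r), eps)
    beta_new <- stats::lm.wfit(X, y, w)$coefficients
    beta_new[is.na(beta_new)] <- 0
    obj_new <- sum(abs(y - X %*% beta_new))
    if (obj_new <= obj) beta <- beta_new
    if (abs(obj - obj_new) < 1e-8 * (1 + obj)) break
    obj <- min(obj, obj_new)
  }
  stats::setNames(as.numeric(beta), c("c0", "c1", "c2"))
}

#' Apply calibration coefficients to a composite
#'
#' `dn' = clamp(c0 + c1*dn + c2*dn^2, 0, 63)`; pixels with `dn = 0` stay 0
#' regardless of the intercept (no false lights), and the output is kept
#' fractional (no re-rounding). Warns when the coefficients describe a
#' non-monotone map on `[0, 63]`.
#'
#' @param grid A [composite_grid()].
#' @param coeffs Numeric `c(c0, c1, c2)`.
#' @return A calibrated [composite_grid()].
#' @export
apply_calibration <- function(grid, coeffs) {
  stopifnot(inherits(grid, "composite_grid"), length(coeffs) == 3)
  if (!all(is.finite(coeffs)))
    stop("calibration coefficients must be finite", call. = FALSE)
  c0 <- coeffs[1]; c1 <- coeffs[2]; c2 <- coeffs[3]
  # derivative c1 + 2*c2*x is linear; check at both ends of [0, 63]
  if (min(c1, c1 + 126 * c2) < 0)
    warning(sprintf("calibration map (%.4g, %.4g, %.4g) is non-monotone on [0, 63]",
                    c0, c1, c2), call. = FALSE)
  dn <- grid$dn
  out <- pmin(pmax(c0 + c1 * dn + c2 * dn^2, 0), 63)
  out[dn == 0] <- 0
  composite_grid(out, grid$grid, grid$year, grid$satellite)
}

#' Intercalibrate a composite stack onto a reference year
#'
#' Every non-reference year is mapped onto the reference year's DN scale by a
#' median-regression quadratic fitted on its stable pixels; the reference
#' grid passes through unchanged with coefficients exactly `(0, 1, 0)`. The
#' default reference is the middle year of the stack, which minimizes
#' extrapolation at both ends of the series.
#'
#' @param stack Year-ordered list of [composite_grid()] objects.
#' @param reference_year Calendar year to calibrate onto (default: middle).
#' @param trim,k,max_iter Stable-pixel trimming options, see
#'   [select_stable_pixels()].
#' @param fallback_identity When a year cannot be calibrated (too few co-lit
#'   pixels, or a degenerate fit as in an all-saturated grid), pass it
#'   through with identity coefficients and a warning instead of erroring.
#'   Off by default; the pipeline enables it so fully dark or fully
#'   saturated worlds still flow through.
#' @return A list with `stack` (calibrated) and `model` (class
#'   `calibration_model`: reference year, per-year coefficients and fit
#'   diagnostics).
#' @export
calibrate_stack <- function(stack, reference_year = NULL, trim = FALSE,
                            k = 3, max_iter = 5L, fallback_identity = FALSE) {
  yrs <- check_stack(stack)
  if (is.null(reference_year))
    reference_year <- yrs[(length(yrs) + 1L) %/% 2L]
  if (!reference_year %in% yrs)
    stop("reference_year ", reference_year, " not in stack", call. = FALSE)
  ref <- stack[[match(reference_year, yrs)]]
  coefs <- matrix(NA_real_, length(stack), 3,
                  dimnames = list(yrs, c("c0", "c1", "c2")))
  n_stable <- integer(length(stack))
  med_abs_resid <- numeric(length(stack))
  out <- vector("list", length(stack))
  for (i in seq_along(stack)) {
    if (yrs[i] == reference_year) {
      coefs[i, ] <- c(0, 1, 0)
      n_stable[i] <- sum(ref$dn > 0, na.rm = TRUE)
      med_abs_resid[i] <- 0
      out[[i]] <- stack[[i]]
      next
    }
    fit <- tryCatch({
      idx <- select_stable_pixels(ref, stack[[i]], trim = trim, k = k,
                                  max_iter = max_iter)
      list(idx = idx, cf = fit_calibration(ref$dn[idx], stack[[i]]$dn[idx]))
    }, error = function(e) {
      if (!fallback_identity) stop(e)
      warning(sprintf("year %d left uncalibrated (%s)", yrs[i],
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(fit)) {
      coefs[i, ] <- c(0, 1, 0)
      n_stable[i] <- 0L
      med_abs_resid[i] <- NA_real_
      out[[i]] <- stack[[i]]
      next
    }
    idx <- fit$idx; cf <- fit$cf
    coefs[i, ] <- cf
    n_stable[i] <- length(idx)
    med_abs_resid[i] <- stats::median(abs(
      ref$dn[idx] - (cf[1] + cf[2] * stack[[i]]$dn[idx] +
                       cf[3] * stack[[i]]$dn[idx]^2)))
    out[[i]] <- apply_calibration(stack[[i]], cf)
  }
  model <- structure(list(reference_year = reference_year, years = yrs,
                          coefficients = coefs, n_stable = n_stable,
                          med_abs_resid = med_abs_resid),
                     class = "calibration_model")
  list(stack = out, model = model)
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> reference year %d\n", x$reference_year))
  df <- data.frame(year = x$years, round(x$coefficients, 5),
                   n_stable = x$n_stable,
                   med_abs_resid = round(x$med_abs_resid, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Serialize a calibration model to JSON
#'
#' @param model A `calibration_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  obj <- list(reference_year = model$reference_year,
              years = model$years,
              coefficients = apply(model$coefficients, 1, as.list),
              n_stable = model$n_stable,
              med_abs_resid = model$med_abs_resid)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
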
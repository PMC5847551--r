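test_that("fit_calibration recovers the identity exactly on clean data", {
  t <- rep(seq(1, 63, length.out = 40), 2)
  cf <- fit_calibration(t, t)
  expect_equal(unname(cf), c(0, 1, 0), tolerance = 1e-6)
})

test_that("fit_calibration enforces its preconditions", {
  expect_error(fit_calibration(1:10, 1:10), ">= 30")
  expect_error(fit_calibration(rep(1, 40), rep(3, 40)), "degenerate")
})

test_that("median regression recovers a noisy quadratic within tolerance", {
  set.seed(1234)
  t <- runif(10000, 0, 63)
  truth <- c(-1, 1.2, -0.003)
  ref <- truth[1] + truth[2] * t + truth[3] * t^2 + rnorm(10000, 0, 1)
  cf <- fit_calibration(ref, t)
  expect_lt(abs(cf["c0"] - truth[1]), 0.2)
  expect_lt(abs(cf["c1"] - truth[2]), 0.02)
  expect_lt(abs(cf["c2"] - truth[3]), 5e-4)
})

test_that("median fit resists outliers that break least squares", {
  set.seed(77)
  t <- runif(5000, 0, 63)
  ref <- t  # truth is the identity
  shift <- seq_along(t) <= 500  # 10% outliers
  ref[shift] <- ref[shift] + 40
  cf <- fit_calibration(ref, t)
  expect_lt(abs(cf["c0"]), 0.2)
  expect_lt(abs(cf["c1"] - 1), 0.02)
  expect_lt(abs(cf["c2"]), 5e-4)
  ols <- unname(stats::lm(ref ~ t + I(t^2))$coefficients)
  ols_ok <- abs(ols[1]) <= 0.2 && abs(ols[2] - 1) <= 0.02 &&
    abs(ols[3]) <= 5e-4
  expect_false(ols_ok)
})

test_that("fit_calibration is deterministic for fixed input", {
  set.seed(5)
  t <- runif(500, 0, 63)
  ref <- 2 + 0.9 * t + rnorm(500)
  expect_identical(fit_calibration(ref, t), fit_calibration(ref, t))
})

test_that("stable-pixel selection needs co-lit pixels and supports trimming", {
  g <- grid_spec(40, 40)
  zeros <- composite_grid(matrix(0, 40, 40), g, 2000)
  lit <- composite_grid(matrix(30, 40, 40), g, 2001)
  expect_error(select_stable_pixels(zeros, lit), "insufficient")
  set.seed(21)
  ref_dn <- matrix(runif(1600, 5, 60), 40, 40)
  ref <- composite_grid(ref_dn, g, 2000)
  tgt <- composite_grid(ref_dn, g, 2001)
  expect_length(select_stable_pixels(ref, tgt), 1600)  # all co-lit selected
  # 5% of pixels genuinely change (+30 DN): trimming excludes >= 90% of them
  change <- sample(1600, 80)
  tgt_dn <- pmin(ref_dn + ifelse(seq_len(1600) %in% change, 30, 0), 63)
  tgt2 <- composite_grid(matrix(tgt_dn, 40, 40), g, 2001)
  kept <- select_stable_pixels(ref, tgt2, trim = TRUE)
  expect_lt(sum(change %in% kept) / length(change), 0.1)
})

test_that("apply_calibration clamps, preserves zeros and warns on non-monotone maps", {
  g <- flat_grid(0, 3, 3)
  g$dn[1, ] <- c(60, 10, 5)
  out <- apply_calibration(g, c(0, 1.1, 0))
  expect_equal(out$dn[1, 1], 63)      # clamped
  expect_equal(out$dn[1, 2], 11)      # fractional preserved
  expect_equal(out$dn[2, 1], 0)
  shifted <- apply_calibration(g, c(5, 1, 0))
  expect_equal(shifted$dn[3, 3], 0)   # zero preservation beats the intercept
  expect_warning(apply_calibration(g, c(0, 1, -0.02)), "non-monotone")
  expect_error(apply_calibration(g, c(NA, 1, 0)), "finite")
})

test_that("calibrate_stack maps distorted years back onto the reference scale", {
  b <- small_bundle()
  cal <- calibrate_stack(b$observed)
  ref_year <- cal$model$reference_year
  expect_equal(ref_year, 1995)  # middle of 1992-1999
  i_ref <- match(ref_year, cal$model$years)
  expect_equal(unname(cal$model$coefficients[i_ref, ]), c(0, 1, 0))
  expect_identical(cal$stack[[i_ref]]$dn, b$observed[[i_ref]]$dn)
  # calibrated stack approximates the truth on stable (unsaturated) pixels
  noise_sd <- b$params$distortion$noise_sd
  for (i in seq_along(cal$stack)) {
    truth <- b$truth[[i]]$dn
    stable <- truth > 0 & truth < 55 & b$observed[[i]]$dn < 63
    rmse <- sqrt(mean((cal$stack[[i]]$dn[stable] - truth[stable])^2))
    expect_lt(rmse, 1.6 * max(noise_sd, 1))
  }
})

test_that("calibrating identical grids yields identity coefficients", {
  g <- grid_spec(20, 20)
  set.seed(8)
  dn <- matrix(runif(400, 1, 63), 20, 20)
  stack <- lapply(1:3, function(i) composite_grid(dn, g, 1999L + i))
  cal <- calibrate_stack(stack)
  for (i in 1:3)
    expect_equal(unname(cal$model$coefficients[i, ]), c(0, 1, 0),
                 tolerance = 1e-6)
})

test_that("a single-year stack passes through with an identity model", {
  g <- flat_grid(10, 8, 8, year = 2005)
  cal <- calibrate_stack(list(g))
  expect_identical(cal$stack[[1]]$dn, g$dn)
  expect_equal(unname(cal$model$coefficients[1, ]), c(0, 1, 0))
})

test_that("calibration is idempotent against the same reference", {
  b <- small_bundle()
  cal1 <- calibrate_stack(b$observed)
  cal2 <- calibrate_stack(cal1$stack, reference_year = cal1$model$reference_year)
  for (i in seq_along(cal1$stack)) {
    # re-fitted maps on already-calibrated data stay near the identity, so
    # DN values barely move
    delta <- max(abs(cal2$stack[[i]]$dn - cal1$stack[[i]]$dn))
    expect_lt(delta, 1.5)
  }
})

test_that("noiseless monotone affine distortions are recovered exactly", {
  # the inverse of an affine map is affine, so the quadratic median fit must
  # recover it to solver precision; genuinely quadratic distortions are only
  # invertible approximately (checked by composition below)
  g <- grid_spec(16, 16)
  dn <- matrix(seq(0, 63, length.out = 256), 16, 16)
  ref <- composite_grid(dn, g, 2000)
  for (cf in list(c(2, 0.9, 0), c(-3, 1.2, 0))) {
    tgt <- apply_distortion(ref, cf[1], cf[2], cf[3])
    ok <- ref$dn > 0 & tgt$dn > 0 & tgt$dn < 63
    fitted <- fit_calibration(ref$dn[ok], tgt$dn[ok])
    # inverse-consistent truth: t = cf1 + cf2*r  =>  r = (t - cf1)/cf2
    expect_equal(unname(fitted), c(-cf[1] / cf[2], 1 / cf[2], 0),
                 tolerance = 1e-3)
  }
  # mild quadratic: composition back to reference within 0.2 DN
  tgt <- apply_distortion(ref, -1, 1.2, -0.003)
  ok <- ref$dn > 0 & tgt$dn > 0 & tgt$dn < 63
  fitted <- fit_calibration(ref$dn[ok], tgt$dn[ok])
  back <- fitted[1] + fitted[2] * tgt$dn[ok] + fitted[3] * tgt$dn[ok]^2
  expect_lt(sqrt(mean((back - ref$dn[ok])^2)), 0.2)
  expect_lt(max(abs(back - ref$dn[ok])), 0.5)
})

test_that("calibration models serialize to JSON", {
  b <- small_bundle()
  cal <- calibrate_stack(b$observed)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(cal$model, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$reference_year, cal$model$reference_year)
  expect_length(back$coefficients, length(b$observed))
})
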
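test_that("two-point calibration is the exact analytic line", {
  m <- fit_internal_calibration(-100, 50, rho_fat = 0, rho_muscle = 150)
  expect_equal(m$slope, 1.0)
  expect_equal(m$intercept, 100.0)

  # identity case: references equal to the HU values
  m2 <- fit_internal_calibration(-80, 60, rho_fat = -80, rho_muscle = 60)
  expect_equal(m2$slope, 1.0)
  expect_equal(m2$intercept, 0.0)

  # random admissible inputs agree with a least-squares fit through the
  # two anchor points to machine precision
  set.seed(11)
  for (i in 1:20) {
    hf <- runif(1, -150, -60); hm <- runif(1, 20, 90)
    rf <- runif(1, -80, -20); rm_ <- runif(1, 10, 80)
    m3 <- fit_internal_calibration(hf, hm, rf, rm_)
    fit <- lm(c(rf, rm_) ~ c(hf, hm))
    expect_equal(m3$intercept, unname(coef(fit)[1]), tolerance = 1e-9)
    expect_equal(m3$slope, unname(coef(fit)[2]), tolerance = 1e-9)
    # anchor identities hold exactly for every admissible model
    expect_equal(apply_calibration(m3, hf), rf, tolerance = 1e-12)
    expect_equal(apply_calibration(m3, hm), rm_, tolerance = 1e-12)
  }
})

test_that("insufficient fat/muscle contrast is rejected", {
  expect_error(fit_internal_calibration(-10, -5), "degenerate tissue contrast")
  expect_error(fit_internal_calibration(50, -100), "degenerate tissue contrast")
})

test_that("calibration application is the plain affine map", {
  m <- fit_internal_calibration(-100, 50, rho_fat = -50, rho_muscle = 40)
  expect_equal(apply_calibration(fit_internal_calibration(0, 150, 0, 150), 120), 120)
  expect_equal(apply_calibration(m, m$hu_fat), m$rho_fat)
  expect_error(apply_calibration(m, NaN), "finite")
})

test_that("the full pipeline recovers phantom truth", {
  # noise-free: exact to better than 1 mg/cc
  p <- make_phantom(density = 130)
  r <- measure_vbmd(p$volume)
  expect_lt(abs(r$vbmd_mgcc - 130), 1)
  expect_equal(as.character(r$category), "normal")

  # with 15-HU noise the 5-seed mean stays within 3 mg/cc (the deeper
  # 20-seed version runs in the acceptance suite)
  ests <- vapply(1:5, function(s) {
    measure_vbmd(make_phantom(density = 130, noise = 15, seed = s)$volume)$vbmd_mgcc
  }, numeric(1))
  expect_lt(abs(mean(ests) - 130), 3)
})

test_that("vBMD increases monotonically with true density", {
  ests <- vapply(c(60, 110, 160), function(d) {
    measure_vbmd(make_phantom(density = d)$volume)$vbmd_mgcc
  }, numeric(1))
  expect_true(all(diff(ests) > 0))
})

test_that("internal calibration cancels the device response", {
  dev_a <- device_model("A", hu_fat = -100, hu_muscle = 50)
  dev_b <- device_model("B", hu_fat = -90, hu_muscle = 60)
  va <- measure_vbmd(make_phantom(density = 100, device = dev_a)$volume)
  vb <- measure_vbmd(make_phantom(density = 100, device = dev_b)$volume)
  # raw trabecular HU differ between devices ...
  expect_gt(abs(tidy(va)$hu_trab - tidy(vb)$hu_trab), 2)
  # ... but the internally calibrated densities agree
  expect_lt(abs(va$vbmd_mgcc - vb$vbmd_mgcc), 2)
  expect_lt(abs(va$vbmd_mgcc - 100), 1)
})

test_that("within one device HU and pipeline vBMD are collinear", {
  densities <- c(60, 85, 110, 135, 160)
  rows <- lapply(densities, function(d) {
    tidy(measure_vbmd(make_phantom(density = d)$volume))
  })
  df <- do.call(rbind, rows)
  reg <- fit_device_regression(df$hu_trab, df$vbmd_mgcc, device = "synthetic:A")
  expect_equal(reg$pearson_r, 1.0, tolerance = 1e-9)

  # noisy acquisitions stay strongly correlated
  noisy <- lapply(seq_along(densities), function(i) {
    tidy(measure_vbmd(make_phantom(density = densities[i], noise = 15,
                                   seed = 100 + i)$volume))
  })
  dfn <- do.call(rbind, noisy)
  expect_gt(pearson_r(dfn$hu_trab, dfn$vbmd_mgcc), 0.85)
})

test_that("device regression matches the raw-sums closed form", {
  x <- 1:5
  exact <- fit_device_regression(x, 2 * x + 5)
  expect_equal(exact$slope, 2); expect_equal(exact$intercept, 5)
  expect_equal(exact$pearson_r, 1.0)
  anti <- fit_device_regression(x, -x + 3)
  expect_equal(anti$pearson_r, -1.0)

  set.seed(21)
  hu <- rnorm(20, 150, 40)
  vb <- 0.6 * hu + 10 + rnorm(20, 0, 8)
  reg <- fit_device_regression(hu, vb, "dev")
  o <- ols_oracle(hu, vb)
  expect_equal(reg$slope, o$slope, tolerance = 1e-10)
  expect_equal(reg$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(reg$pearson_r, o$r, tolerance = 1e-10)

  expect_error(fit_device_regression(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(fit_device_regression(1:2, 1:2), ">= 3")
})

test_that("pipeline errors carry their stage tag", {
  vol <- flat_volume(hu = -1000, dims = c(8, 60, 60))
  expect_error(measure_vbmd(vol), "\\[locate\\]")
})
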
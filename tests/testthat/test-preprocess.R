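test_that("resampling matches a naive interpolation oracle", {
  withr::with_seed(4, {
    wl <- sort(runif(40, 400, 900))
    v <- runif(40, 0, 0.6)
  })
  s <- spectrum(wl, v)
  grid <- seq(ceiling(min(wl)), floor(max(wl)), by = 7)
  out <- resample_to_grid(s, grid)
  # independent piecewise-linear evaluation
  naive <- vapply(grid, function(g) {
    i <- max(which(wl <= g))
    if (wl[i] == g) return(v[i])
    v[i] + (v[i + 1] - v[i]) * (g - wl[i]) / (wl[i + 1] - wl[i])
  }, numeric(1))
  expect_equal(out$values, naive, tolerance = 1e-12)

  # pass-through where grid coincides with input
  s2 <- spectrum(500:510, seq(0.1, 0.2, length.out = 11))
  expect_equal(resample_to_grid(s2, 500:510)$values, s2$values)
  # linear midpoint
  s3 <- spectrum(c(700, 702), c(0.2, 0.4))
  expect_equal(resample_to_grid(s3, 701)$values, 0.3)
  # duplicated input wavelengths collapse to their mean first
  s4 <- structure(list(wavelengths = c(700, 700, 702),
                       values = c(0.1, 0.3, 0.4), kind = "reflectance",
                       metadata = list()), class = "spectrum")
  expect_equal(resample_to_grid(s4, 701)$values, 0.3)
  expect_error(resample_to_grid(s3, 699:702), "extrapolation|span")
})

test_that("Savitzky-Golay smoothing reproduces low-degree polynomials", {
  grid <- 400:500
  for (case in list(c(11, 2), c(21, 3))) {
    w <- case[1]; p <- case[2]
    x <- (grid - 450) / 50
    poly <- 0.3 + 0.1 * x + 0.05 * x^2
    s <- spectrum(grid, poly)
    expect_equal(savgol_smooth(s, w, p)$values, poly, tolerance = 1e-10)
  }
  const <- spectrum(grid, rep(0.4, length(grid)))
  expect_equal(savgol_smooth(const)$values, rep(0.4, length(grid)))
  expect_error(savgol_smooth(spectrum(grid, rep(0.2, 101)), window = 10), "odd")
  expect_error(savgol_smooth(spectrum(c(1, 2, 4, 8) + 400, rep(0.2, 4))),
               "uniform")
})

test_that("interior smoothing equals a direct local least-squares fit", {
  withr::with_seed(8, v <- runif(61, 0, 0.5))
  grid <- 600:660
  sm <- savgol_smooth(spectrum(grid, v), 11, 2)
  for (i in c(20, 31, 45)) {
    idx <- (i - 5):(i + 5)
    fit <- lm(y ~ x + I(x^2), data = data.frame(x = grid[idx] - grid[i],
                                                y = v[idx]))
    expect_equal(sm$values[i], unname(coef(fit)[1]), tolerance = 1e-10)
  }
})

test_that("first derivative is exact for linear spectra and locates a logistic inflection", {
  grid <- 400:900
  lin <- spectrum(grid, 0.05 + 0.001 * (grid - 400))
  d <- first_derivative(lin)
  expect_equal(d$values, rep(0.001, length(grid)), tolerance = 1e-12)
  expect_identical(d$kind, "first_derivative")

  const <- spectrum(grid, rep(0.3, length(grid)))
  expect_equal(first_derivative(const)$values, rep(0, length(grid)))

  lg <- logistic_spectrum(grid, inflection = 725)
  d <- first_derivative(lg$refl)
  expect_equal(d$wavelengths[which.max(d$values)], 725, tolerance = 1)
  expect_error(first_derivative(spectrum(c(500, 510), c(0.1, 0.2))),
               "3 bands")
  expect_error(first_derivative(lg$deriv), "reflectance")
})

test_that("smoothing and differentiation are linear operators", {
  grid <- 500:600
  withr::with_seed(12, {
    x <- runif(101, 0, 0.4)
    y <- runif(101, 0, 0.4)
  })
  a <- 0.7; b <- 0.25
  sx <- spectrum(grid, x); sy <- spectrum(grid, y)
  sxy <- spectrum(grid, a * x + b * y)
  expect_equal(savgol_smooth(sxy)$values,
               a * savgol_smooth(sx)$values + b * savgol_smooth(sy)$values,
               tolerance = 1e-10)
  expect_equal(first_derivative(sxy)$values,
               a * first_derivative(sx)$values +
                 b * first_derivative(sy)$values,
               tolerance = 1e-10)
})

test_that("derivative of a smoothed quadratic matches the analytic derivative", {
  grid <- 400:600
  x <- (grid - 500) / 100
  s <- spectrum(grid, 0.2 + 0.1 * x + 0.04 * x^2)
  sm <- savgol_smooth(s, 11, 2)
  d <- first_derivative(sm)
  analytic <- (0.1 + 0.08 * x) / 100
  interior <- 7:195
  expect_equal(d$values[interior], analytic[interior], tolerance = 1e-8)
})

test_that("derivative_table matches per-spectrum central differences", {
  cfg <- sim_config(n_per_group = 3, stages = "branching", seed = 5)
  tb <- simulate_experiment(cfg)$branching
  dt <- derivative_table(tb)
  for (i in c(1, 4)) {
    one <- first_derivative(spectrum(tb$wavelengths, tb$spectra[i, ]))
    expect_equal(unname(dt$spectra[i, ]), one$values, tolerance = 1e-12)
  }
})

test_that("savgol derivative option agrees with central difference on smooth data", {
  lg <- logistic_spectrum(500:900)
  d1 <- first_derivative(lg$refl, method = "central")
  d2 <- first_derivative(lg$refl, method = "savgol")
  expect_equal(d2$wavelengths[which.max(d2$values)],
               d1$wavelengths[which.max(d1$values)], tolerance = 1)
})
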
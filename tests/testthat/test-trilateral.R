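test_that("logistic spectra yield the analytic red-edge position and area", {
  # closed-form: for R = base + (plateau-base)*logistic((l-m)/s), the FDR
  # integral over [a, b] is R(b) - R(a)
  lg <- logistic_spectrum(350:1350, inflection = 725, scale = 10,
                          base = 0.05, plateau = 0.5)
  tp <- extract_trilateral(lg$refl, lg$deriv)
  expect_equal(unname(tp["lambda_r"]), 725, tolerance = 1)
  f <- logistic_refl_fun(725, 10, 0.05, 0.5)
  expect_equal(unname(tp["SDr"]), f(780) - f(680), tolerance = 0.01 * 0.45)
  expect_equal(unname(tp["Dr"]), 0.45 / 40, tolerance = 1e-3)
})

test_that("constant reflectance gives zero amplitudes and flagged ratios", {
  grid <- 350:1350
  const <- spectrum(grid, rep(0.2, length(grid)))
  dz <- spectrum(grid, rep(0, length(grid)), kind = "first_derivative")
  tp <- extract_trilateral(const, dz)
  for (nm in c("Dr", "Db", "Dy", "SDr", "SDb", "SDy")) {
    expect_equal(unname(tp[nm]), 0)
  }
  expect_true(is.na(tp["SDr_over_SDb"]))
  expect_true(is.na(tp["SDr_minus_SDb_norm"]))
  expect_equal(unname(tp["Rg"]), 0.2)
})

test_that("combination indices follow their printed formulas", {
  # plant Rg = 0.12 (at 530) and Rr = 0.04 (at 670) with a simple shape
  grid <- 350:1350
  v <- rep(0.08, length(grid))
  v[grid >= 510 & grid <= 560] <- 0.10
  v[grid == 530] <- 0.12
  v[grid >= 640 & grid <= 700] <- 0.05
  v[grid == 670] <- 0.04
  refl <- spectrum(grid, v)
  tp <- extract_trilateral(refl, first_derivative(refl))
  expect_equal(unname(tp["Rg"]), 0.12)
  expect_equal(unname(tp["Rr"]), 0.04)
  expect_equal(unname(tp["Rg_over_Rr"]), 3)
  expect_equal(unname(tp["Rg_minus_Rr_norm"]), 0.5)
  expect_equal(unname(tp["SDr_minus_SDb"]),
               unname(tp["SDr"] - tp["SDb"]))
})

test_that("red_edge_summary matches an exhaustive scan and breaks ties left", {
  grid <- 600:800
  withr::with_seed(21, d <- runif(201, -0.001, 0.01))
  ds <- spectrum(grid, d, kind = "first_derivative")
  out <- red_edge_summary(ds, c(680, 780))
  idx <- which(grid >= 680 & grid <= 780)
  # brute-force scan oracle
  best <- idx[1]
  for (i in idx) if (d[i] > d[best]) best <- i
  expect_equal(unname(out["lambda_r"]), grid[best])
  expect_equal(unname(out["Dr"]), d[best])
  area <- sum((d[idx][-1] + d[idx][-length(idx)]) / 2)
  expect_equal(unname(out["SDr"]), area, tolerance = 1e-12)

  # two equal maxima -> the shorter wavelength wins
  d2 <- rep(0, 201); d2[grid == 721] <- 0.01; d2[grid == 728] <- 0.01
  out2 <- red_edge_summary(spectrum(grid, d2, kind = "first_derivative"))
  expect_equal(unname(out2["lambda_r"]), 721)
})

test_that("amplitudes and areas are scale-equivariant, positions are not", {
  lg <- logistic_spectrum(350:1350, inflection = 730)
  tp1 <- extract_trilateral(lg$refl, lg$deriv)
  c_scale <- 0.5
  refl2 <- spectrum(lg$refl$wavelengths, c_scale * lg$refl$values)
  deriv2 <- spectrum(lg$deriv$wavelengths, c_scale * lg$deriv$values,
                     kind = "first_derivative")
  tp2 <- extract_trilateral(refl2, deriv2)
  for (nm in c("Dr", "Db", "Dy", "Rg", "Rr", "SDr", "SDb", "SDy")) {
    expect_equal(unname(tp2[nm]), c_scale * unname(tp1[nm]),
                 tolerance = 1e-12)
  }
  for (nm in c("lambda_r", "lambda_b", "lambda_y", "lambda_g", "lambda_v",
               "Rg_over_Rr", "Rg_minus_Rr_norm", "SDr_over_SDb",
               "SDr_minus_SDb_norm", "SDr_minus_SDy_norm")) {
    expect_equal(unname(tp2[nm]), unname(tp1[nm]), tolerance = 1e-12)
  }
})

test_that("grid refinement moves positions by at most one coarse step", {
  f <- logistic_refl_fun(727, 12, 0.06, 0.48)
  coarse <- seq(350, 1350, by = 2)
  fine <- seq(350, 1350, by = 1)
  tp_c <- extract_trilateral(spectrum(coarse, f(coarse)),
                             first_derivative(spectrum(coarse, f(coarse))))
  tp_f <- extract_trilateral(spectrum(fine, f(fine)),
                             first_derivative(spectrum(fine, f(fine))))
  expect_lte(abs(tp_c["lambda_r"] - tp_f["lambda_r"]), 2)
  expect_lte(abs(tp_c["SDr"] - tp_f["SDr"]) / abs(tp_f["SDr"]), 0.01)
})

test_that("extraction validates grids and windows", {
  lg <- logistic_spectrum(350:1350)
  other <- logistic_spectrum(360:1350)
  expect_error(extract_trilateral(lg$refl, other$deriv), "grid")
  expect_error(extract_trilateral(lg$refl, lg$deriv,
                                  edge_windows(red_edge = c(100, 200))),
               "window")
  expect_error(edge_windows(red_edge = c(780, 680)), "interval")
  expect_equal(length(TRILATERAL_NAMES), 20)
})
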
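test_that("metrics match their defining formulas", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  y <- c(2, 4, 6)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_true(is.na(r_squared(rep(2, 4), 1:4)))

  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  withr::with_seed(9, {
    y <- rnorm(20); p <- rnorm(20)
  })
  expect_equal(rmse(3 * y, 3 * p), 3 * rmse(y, p), tolerance = 1e-12)

  expect_equal(amplitude_of_variation(40, 40), 0)
  expect_equal(amplitude_of_variation(50, 40), 25)
  expect_equal(amplitude_of_variation(20, 40), -50)
  expect_true(is.na(amplitude_of_variation(5, 0)))
})

test_that("metrics agree with one-line re-implementations on random vectors", {
  for (k in 1:100) {
    withr::with_seed(1000 + k, {
      n <- sample(5:50, 1)
      y <- rnorm(n, sd = runif(1, 0.1, 10))
      p <- y + rnorm(n)
    })
    expect_equal(r_squared(y, p),
                 1 - sum((y - p)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-12)
    expect_equal(rmse(y, p), sqrt(sum((y - p)^2) / length(y)),
                 tolerance = 1e-12)
    expect_equal(amplitude_of_variation(p[1], y[1]),
                 (p[1] - y[1]) / y[1] * 100, tolerance = 1e-12)
  }
})

test_that("train/test split is seeded, disjoint, exhaustive, 3:1 by default", {
  sp <- split_train_test(80, seed = 7)
  expect_length(sp$train, 60)
  expect_length(sp$test, 20)
  expect_setequal(c(sp$train, sp$test), 1:80)
  expect_identical(sp, split_train_test(80, seed = 7))
  expect_false(identical(sp$test, split_train_test(80, seed = 8)$test))
  sp8 <- split_train_test(8)
  expect_length(sp8$train, 6)
  expect_length(sp8$test, 2)
  expect_error(split_train_test(5), "too few")
})

test_that("all three model kinds handle degenerate and exact targets", {
  withr::with_seed(2, X <- matrix(runif(40), 20, 2))
  # constant target -> constant prediction for every kind
  for (kind in c("SVR", "RFR", "PLSR")) {
    m <- fit_model(kind, X, rep(3.5, 20))
    expect_equal(predict(m, X), rep(3.5, 20))
  }
  # exact linear single-feature target: PLSR recovers it
  x <- matrix(seq(0, 1, length.out = 24), ncol = 1)
  y <- 2 * x[, 1] + 1
  m <- fit_model("PLSR", x, y)
  expect_lt(rmse(y, predict(m, x)), 1e-6)
  # multi-feature exact linear target
  withr::with_seed(3, X2 <- matrix(rnorm(60), 20, 3))
  y2 <- X2 %*% c(1, -2, 0.5) + 4
  m2 <- fit_model("PLSR", X2, as.numeric(y2))
  expect_lt(rmse(as.numeric(y2), predict(m2, X2)), 1e-6)
})

test_that("RFR and SVR are deterministic under a fixed seed", {
  withr::with_seed(4, {
    X <- matrix(rnorm(100), 25, 4)
    y <- X[, 1] + rnorm(25, 0, 0.2)
  })
  p1 <- predict(fit_model("RFR", X, y, seed = 11), X)
  p2 <- predict(fit_model("RFR", X, y, seed = 11), X)
  expect_identical(p1, p2)
  s1 <- predict(fit_model("SVR", X, y, seed = 11), X)
  s2 <- predict(fit_model("SVR", X, y, seed = 11), X)
  expect_identical(s1, s2)
})

test_that("evaluate_model reports coherent train/test scores", {
  withr::with_seed(5, {
    X <- matrix(rnorm(200), 50, 4)
    y <- X[, 1] - X[, 2] + rnorm(50, 0, 0.1)
  })
  sp <- split_train_test(50, seed = 1)
  row <- evaluate_model("PLSR", X, y, sp, seed = 1)
  expect_lte(row$r2_train, 1)
  expect_gte(row$rmse_test, 0)
  expect_equal(row$n_train, 38)
  expect_equal(row$n_test, 12)
  expect_gt(row$r2_test, 0.8)
})

test_that("feature selection fitted on train never sees test labels", {
  cfg <- sim_config(n_per_group = 12, stages = "budding", seed = 31)
  tb <- simulate_experiment(cfg)$budding
  refl <- smooth_table(tb, 11, 2)
  deriv <- derivative_table(refl)
  tri <- trilateral_table(refl, derivative = deriv)
  pcfg <- pipeline_config(stride = 20, spa_stride = 50, spa_nmax = 3,
                          seed = 2)
  sp <- split_train_test(24, seed = 2)
  sel1 <- fit_selectors(refl, deriv, tri, "SPAD", sp$train, pcfg)
  # shuffle the test labels only: fitted selectors must not change
  refl2 <- refl
  perm <- withr::with_seed(99, sample(sp$test))
  refl2$physiology$SPAD[sp$test] <- refl$physiology$SPAD[perm]
  deriv2 <- deriv
  deriv2$physiology <- refl2$physiology
  sel2 <- fit_selectors(refl2, deriv2, tri, "SPAD", sp$train, pcfg)
  expect_identical(sel1$os1, sel2$os1)
  expect_identical(sel1$os2, sel2$os2)
  expect_identical(sel1$tp, sel2$tp)
  expect_identical(sel1$ndvi$lambda1, sel2$ndvi$lambda1)
  expect_identical(sel1$fdndvi$lambda2, sel2$fdndvi$lambda2)
})

test_that("build_features produces the documented column counts", {
  cfg <- sim_config(n_per_group = 12, stages = "budding", seed = 13)
  tb <- simulate_experiment(cfg)$budding
  refl <- smooth_table(tb, 11, 2)
  deriv <- derivative_table(refl)
  tri <- trilateral_table(refl, derivative = deriv)
  pcfg <- pipeline_config(stride = 10, spa_stride = 50, spa_nmax = 3)
  sel <- fit_selectors(refl, deriv, tri, "SPAD", 1:24, pcfg)
  expect_equal(ncol(build_features("OS1", refl, deriv, tri, sel)), 10)
  expect_equal(ncol(build_features("FDS1", refl, deriv, tri, sel)), 10)
  expect_equal(ncol(build_features("NDVI", refl, deriv, tri, sel)), 1)
  expect_equal(ncol(build_features("OS2", refl, deriv, tri, sel)),
               length(sel$os2))
  # impossible TP threshold -> empty-set error
  sel_bad <- sel
  sel_bad$tp <- character(0)
  expect_error(build_features("TP", refl, deriv, tri, sel_bad), "empty TP")
})
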
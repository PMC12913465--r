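test_that("correlation spectrum matches hand-computed Pearson r", {
  X <- cbind(b1 = c(1, 2, 3, 4), b2 = c(4, 3, 2, 1), b3 = rep(2, 4))
  y <- c(1, 3, 2, 4)
  cs <- correlation_spectrum(X, c(500, 510, 520), y, "toy")
  expect_equal(cs$r[1], 0.8)
  expect_equal(cs$r[2], -0.8)
  expect_equal(cs$r[3], 0)          # zero-variance band flagged, r = 0
  expect_true(cs$zero_variance[3])
  # self-correlation
  cs2 <- correlation_spectrum(X, c(500, 510, 520), X[, 1], "self")
  expect_equal(cs2$r[1], 1)
  expect_error(correlation_spectrum(X, c(500, 510, 520), rep(5, 4)),
               "constant")
})

test_that("independent noise yields uniformly small correlations", {
  withr::with_seed(31, {
    X <- matrix(rnorm(500 * 30), 500, 30)
    y <- rnorm(500)
  })
  cs <- correlation_spectrum(X, 1:30, y)
  expect_lt(max(abs(cs$r)), 0.3)
})

test_that("top_k_bands equals a full sort and breaks ties left", {
  withr::with_seed(13, r <- runif(50, -1, 1))
  wl <- seq(400, by = 10, length.out = 50)
  cs <- structure(list(wavelengths = wl, r = r, n = 20, indicator = "x",
                       zero_variance = rep(FALSE, 50)),
                  class = "correlation_spectrum")
  top <- top_k_bands(cs, 10)
  ord <- order(-abs(r), wl)
  expect_equal(top$wavelength, wl[ord[1:10]])
  expect_equal(top$r, r[ord[1:10]])
  expect_equal(nrow(top_k_bands(cs, 1)), 1)
  # all-equal |r| -> the k shortest wavelengths
  cs$r <- rep(0.5, 50)
  expect_equal(top_k_bands(cs, 5)$wavelength, wl[1:5])
  expect_error(top_k_bands(cs, 51), "exceeds")
})

test_that("spa_select equals the Gram-Schmidt oracle on random matrices", {
  for (case in 1:25) {
    withr::with_seed(200 + case, {
      n <- sample(6:12, 1)
      B <- sample(8:20, 1)
      X <- matrix(rnorm(n * B), n, B)
      k0 <- sample(B, 1)
      N <- sample(2:min(n - 2, B, 6), 1)
    })
    expect_equal(spa_select(X, k0, N), naive_spa(X, k0, N),
                 info = sprintf("case %d", case))
  }
})

test_that("SPA respects orthogonality structure and eliminates collinearity", {
  # orthogonal columns with norms 3 > 2 > 1: picks in norm order
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))[, 1:3]
  X <- Q %*% diag(c(3, 2, 1))
  sel <- spa_select(X, 1, 3, standardize = FALSE)
  expect_equal(sel, c(1, 2, 3))
  # duplicated column has zero residual: never picked before independent ones
  withr::with_seed(17, X2 <- matrix(rnorm(8 * 4), 8, 4))
  X2 <- cbind(X2, X2[, 1])
  sel2 <- spa_select(X2, 1, 4, standardize = FALSE)
  expect_false(5 %in% sel2)
  # degenerate start column errors with the iteration named
  X3 <- cbind(rep(0, 5), matrix(rnorm(15), 5, 3))
  expect_error(spa_select(X3, 1, 2, standardize = FALSE), "zero norm")
})

test_that("SPA residual norms are non-increasing and picks independent", {
  for (case in 1:10) {
    withr::with_seed(300 + case, X <- matrix(rnorm(10 * 15), 10, 15))
    res <- spa_optimize(X, rnorm(10), N_max = 5, cv_folds = 3, seed = case)
    expect_true(all(diff(res$path) <= 1e-10))
    G <- crossprod(scale(X)[, res$selected])
    expect_gt(rcond(G), 1e-10)
  }
})

test_that("permuting band order permutes SPA output correspondingly", {
  withr::with_seed(55, X <- matrix(rnorm(9 * 12), 9, 12))
  sel <- spa_select(X, 3, 4)
  perm <- withr::with_seed(56, sample(12))
  Xp <- X[, perm]
  selp <- spa_select(Xp, which(perm == 3), 4)
  expect_equal(perm[selp], sel)
})

test_that("spa_optimize recovers a planted two-band linear signal", {
  withr::with_seed(61, {
    X <- matrix(runif(30 * 20, 0, 1), 30, 20)
    bands <- spa_select(X, 7, 2)
    y <- 2 * X[, bands[1]] - 3 * X[, bands[2]] + 1
  })
  res <- spa_optimize(X, y, N_max = 4, cv_folds = 5, seed = 1)
  expect_lt(res$rmsecv, 1e-8)
  # the selection must span the planted bands: OLS on it is exact
  fit <- lm.fit(cbind(1, X[, res$selected]), y)
  expect_lt(sqrt(mean(fit$residuals^2)), 1e-10)
})

test_that("spa_optimize equals an exhaustive re-run on a small grid", {
  withr::with_seed(71, {
    X <- matrix(rnorm(18 * 12), 18, 12)
    y <- X[, 2] - 0.5 * X[, 9] + rnorm(18, 0, 0.1)
  })
  res <- spa_optimize(X, y, N_max = 4, cv_folds = 4, seed = 9)
  # independent exhaustive sweep using the same fold assignment
  folds <- withr::with_seed(9, sample(rep_len(1:4, 18)))
  best <- list(rmse = Inf)
  for (k0 in 1:12) {
    sel_full <- naive_spa(X, k0, 4)
    for (N in 2:4) {
      sel <- sel_full[1:N]
      err2 <- 0
      for (f in 1:4) {
        tr <- folds != f
        cf <- coef(lm(y[tr] ~ X[tr, sel, drop = FALSE]))
        pred <- cbind(1, X[!tr, sel, drop = FALSE]) %*% cf
        err2 <- err2 + sum((y[!tr] - pred)^2)
      }
      rm <- sqrt(err2 / 18)
      if (rm < best$rmse - 1e-12) best <- list(rmse = rm, k0 = k0, N = N,
                                               sel = sel)
    }
  }
  expect_equal(res$rmsecv, best$rmse, tolerance = 1e-10)
  expect_equal(res$selected, best$sel)
})

test_that("correlation spectrum is invariant to affine rescaling of y", {
  withr::with_seed(81, {
    X <- matrix(rnorm(20 * 8), 20, 8)
    y <- rnorm(20)
  })
  r1 <- correlation_spectrum(X, 1:8, y)$r
  r2 <- correlation_spectrum(X, 1:8, 3 * y + 7)$r
  r3 <- correlation_spectrum(X, 1:8, -2 * y)$r
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_equal(r1, -r3, tolerance = 1e-12)
})
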
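#' Coefficient of determination
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. The mean in the
#' denominator is the mean of `y` itself (for a test set, the test-set
#' mean; set `ybar` to use another convention).
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @param ybar Optional mean to use in the denominator.
#' @return R-squared; `NA` when `y` is constant (undefined).
#' @export
r_squared <- function(y, yhat, ybar = mean(y)) {
  ss_tot <- sum((y - ybar)^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((y - yhat)^2) / ss_tot
}

#' Root mean square error
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) sqrt(mean((y - yhat)^2))

#' Amplitude of variation of treatment relative to control
#'
#' `eta = (vT - vCK) / vCK * 100` (percent). Negative values mean the
#' treatment group sits below the control.
#'
#' @param vT Treatment-group value (e.g. group mean).
#' @param vCK Control-group value.
#' @return Percent change; `NA` when `vCK` is 0 (undefined).
#' @export
amplitude_of_variation <- function(vT, vCK) {
  ifelse(vCK == 0, NA_real_, (vT - vCK) / vCK * 100)
}

#' Seeded train/test split
#'
#' Uniform random split without replacement at the given test fraction
#' (default 1/4, i.e. a 3:1 train:test ratio; 80 samples give 60/20).
#' Test size is the floor of `n * test_fraction`.
#'
#' @param n Number of samples (or a [sample_table], whose size is used).
#' @param test_fraction Fraction held out (default 0.25).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_train_test <- function(n, test_fraction = 0.25, seed = 1) {
  if (inherits(n, "sample_table")) n <- nrow(n$spectra)
  n_test <- floor(n * test_fraction)
  if (n_test < 2) stop("too few samples for a meaningful test set")
  test <- sort(withr::with_seed(seed, sample.int(n, n_test)))
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Fit one regression model
#'
#' * `SVR`: epsilon-SVR with RBF kernel, `epsilon = 0.01`; penalty `C`
#'   and kernel width `gamma` picked by a seeded internal 5-fold grid
#'   search (`C` in 0.1/1/10/100, `gamma` on a log grid 1e-3..10).
#'   Features are standardised with training statistics.
#' * `RFR`: random forest, 200 trees, minimum node size 5, seeded
#'   bootstrap.
#' * `PLSR`: partial least squares regression; the number of components
#'   is picked by seeded internal 5-fold CV minimising RMSECV, capped at
#'   `min(10, n_features, n_train - 1)`. With a single feature PLS1 with
#'   one component coincides with simple least squares and is fitted as
#'   such.
#'
#' A constant training target short-circuits to a constant predictor for
#' every kind.
#'
#' @param kind `"SVR"`, `"RFR"` or `"PLSR"`.
#' @param X_train Numeric training matrix (no missing values).
#' @param y_train Training target.
#' @param seed Integer seed controlling internal CV and bootstrap.
#' @param svr_cost,svr_gamma Grids for the SVR search.
#' @param rfr_ntree,rfr_nodesize Random forest settings.
#' @param plsr_max_comp Component cap for PLSR.
#' @return An `hs_model` with a `predict` method.
#' @export
fit_model <- function(kind = c("SVR", "RFR", "PLSR"), X_train, y_train,
                      seed = 1,
                      svr_cost = c(0.1, 1, 10, 100),
                      svr_gamma = 10^seq(-3, 1, length.out = 5),
                      rfr_ntree = 200, rfr_nodesize = 5,
                      plsr_max_comp = 10) {
  kind <- match.arg(kind)
  X_train <- as.matrix(X_train)
  storage.mode(X_train) <- "double"
  if (anyNA(X_train) || anyNA(y_train)) stop("missing values in training data")
  if (stats::sd(y_train) == 0) {
    return(structure(list(kind = kind, constant = y_train[1]),
                     class = "hs_model"))
  }
  fit <- switch(
    kind,
    SVR = .fit_svr(X_train, y_train, seed, svr_cost, svr_gamma),
    RFR = withr::with_seed(seed,
      randomForest::randomForest(x = X_train, y = y_train,
                                 ntree = rfr_ntree,
                                 nodesize = rfr_nodesize)),
    PLSR = .fit_plsr(X_train, y_train, seed, plsr_max_comp)
  )
  structure(list(kind = kind, fit = fit, seed = seed), class = "hs_model")
}

.standardize_fit <- function(X) {
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  list(mu = mu, sd = sds,
       apply = function(Xn) sweep(sweep(Xn, 2, mu), 2, sds, "/"))
}

.fit_svr <- function(X, y, seed, cost_grid, gamma_grid) {
  std <- .standardize_fit(X)
  Xs <- std$apply(X)
  n <- nrow(Xs)
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(5), n)))
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  cv_err <- vapply(seq_len(nrow(grid)), function(g) {
    err2 <- 0
    for (f in unique(folds)) {
      tr <- folds != f
      m <- e1071::svm(Xs[tr, , drop = FALSE], y[tr], type = "eps-regression",
                      kernel = "radial", epsilon = 0.01,
                      cost = grid$cost[g], gamma = grid$gamma[g],
                      scale = FALSE)
      err2 <- err2 + sum((y[!tr] - stats::predict(m, Xs[!tr, , drop = FALSE]))^2)
    }
    sqrt(err2 / n)
  }, numeric(1))
  gbest <- which.min(cv_err)
  m <- e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
                  epsilon = 0.01, cost = grid$cost[gbest],
                  gamma = grid$gamma[gbest], scale = FALSE)
  list(model = m, std = std, cost = grid$cost[gbest],
       gamma = grid$gamma[gbest], cv_rmse = cv_err[gbest])
}

.fit_plsr <- function(X, y, seed, max_comp) {
  std <- .standardize_fit(X)
  Xs <- std$apply(X)
  colnames(Xs) <- paste0("f", seq_len(ncol(Xs)))
  n <- nrow(Xs)
  if (ncol(Xs) == 1) {
    # one feature: PLS1 with one component == simple least squares
    beta <- stats::cov(Xs[, 1], y) / stats::var(Xs[, 1])
    return(list(ols = c(intercept = mean(y) - beta * mean(Xs[, 1]),
                        slope = beta),
                std = std, ncomp = 1))
  }
  # adjacent narrow bands are near-collinear: cap the number of latent
  # components at the effective rank so component extraction stays stable
  eff_rank <- function(M) {
    d <- svd(M, nu = 0, nv = 0)$d
    max(1L, sum(d > 1e-8 * d[1]))
  }
  cap <- min(max_comp, ncol(Xs), n - 1, eff_rank(Xs))
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(5), n)))
  err2 <- numeric(cap)
  for (f in unique(folds)) {
    tr <- folds != f
    cap_f <- min(cap, sum(tr) - 1, eff_rank(Xs[tr, , drop = FALSE]))
    p <- .pls_predict_safe(Xs[tr, , drop = FALSE], y[tr],
                           Xs[!tr, , drop = FALSE], cap_f)
    cap_f <- dim(p)[3]
    for (k in seq_len(cap)) {
      kk <- min(k, cap_f)
      err2[k] <- err2[k] + sum((y[!tr] - p[, 1, kk])^2)
    }
  }
  ncomp <- which.min(sqrt(err2 / n))
  m <- NULL
  while (is.null(m) && ncomp >= 1) {
    m <- tryCatch(mixOmics::pls(Xs, y, ncomp = ncomp, mode = "regression",
                                scale = FALSE),
                  error = function(e) NULL)
    if (is.null(m)) ncomp <- ncomp - 1
  }
  list(model = m, std = std, ncomp = max(ncomp, 1))
}

# fit + predict with progressively fewer components if extraction breaks
# down (degenerate deflation on rank-deficient folds)
.pls_predict_safe <- function(Xtr, ytr, Xte, ncomp) {
  for (k in rev(seq_len(ncomp))) {
    p <- tryCatch({
      m <- mixOmics::pls(Xtr, ytr, ncomp = k, mode = "regression",
                         scale = FALSE)
      stats::predict(m, Xte)$predict
    }, error = function(e) NULL)
    if (!is.null(p)) return(p)
  }
  # last resort: intercept-only prediction
  array(mean(ytr), dim = c(nrow(Xte), 1, 1))
}

#' @export
predict.hs_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (!is.null(object$constant)) {
    return(rep(object$constant, nrow(newdata)))
  }
  switch(object$kind,
         SVR = {
           Xs <- object$fit$std$apply(newdata)
           as.numeric(stats::predict(object$fit$model, Xs))
         },
         RFR = as.numeric(stats::predict(object$fit, newdata)),
         PLSR = {
           Xs <- object$fit$std$apply(newdata)
           if (!is.null(object$fit$ols)) {
             as.numeric(object$fit$ols["intercept"] +
                          object$fit$ols["slope"] * Xs[, 1])
           } else {
             colnames(Xs) <- paste0("f", seq_len(ncol(Xs)))
             p <- stats::predict(object$fit$model, Xs)$predict
             as.numeric(p[, 1, object$fit$ncomp])
           }
         })
}

#' Fit and score one model on a train/test split
#'
#' @param kind Model kind, see [fit_model()].
#' @param X Full design matrix.
#' @param y Full target vector.
#' @param split List with `train`/`test` indices (see
#'   [split_train_test()]).
#' @param seed Seed passed to [fit_model()].
#' @param ... Further arguments to [fit_model()].
#' @return One-row data.frame with train/test R2 and RMSE and sizes.
#' @export
evaluate_model <- function(kind, X, y, split, seed = 1, ...) {
  X <- as.matrix(X)
  m <- fit_model(kind, X[split$train, , drop = FALSE], y[split$train],
                 seed = seed, ...)
  p_tr <- predict(m, X[split$train, , drop = FALSE])
  p_te <- predict(m, X[split$test, , drop = FALSE])
  data.frame(model = kind,
             r2_train = r_squared(y[split$train], p_tr),
             rmse_train = rmse(y[split$train], p_tr),
             r2_test = r_squared(y[split$test], p_te),
             rmse_test = rmse(y[split$test], p_te),
             n_train = length(split$train), n_test = length(split$test),
             seed = seed, stringsAsFactors = FALSE)
}
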
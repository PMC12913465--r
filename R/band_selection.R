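#' Per-band Pearson correlation spectrum
#'
#' Pearson correlation between each band's values and an indicator, the
#' first stage of sensitive-band screening.
#'
#' @param X Samples-by-bands matrix.
#' @param wavelengths Band wavelengths.
#' @param y Indicator values (non-constant, >= 3 samples).
#' @param indicator Indicator name carried in the result.
#' @return `correlation_spectrum`: list with `wavelengths`, `r`, `n`,
#'   `indicator`, `zero_variance` (logical flag per band; such bands get
#'   r = 0).
#' @export
correlation_spectrum <- function(X, wavelengths, y, indicator = "y") {
  stopifnot(ncol(X) == length(wavelengths), nrow(X) == length(y))
  if (nrow(X) < 3) stop("need at least 3 samples")
  if (stats::sd(y) == 0) stop("constant indicator: correlation undefined")
  sds <- apply(X, 2, stats::sd)
  zero_var <- sds == 0
  r <- rep(0, ncol(X))
  if (any(!zero_var)) {
    r[!zero_var] <- as.numeric(stats::cor(X[, !zero_var, drop = FALSE], y))
  }
  structure(list(wavelengths = wavelengths, r = r, n = nrow(X),
                 indicator = indicator, zero_variance = zero_var),
            class = "correlation_spectrum")
}

#' Top-k bands by absolute correlation
#'
#' The `k` bands of largest `|r|`, sorted by `|r|` descending, ties
#' broken toward the shorter wavelength (default k = 10, the size of the
#' OS1/FDS1 feature sets).
#'
#' @param corr A [correlation_spectrum()].
#' @param k Number of bands.
#' @return data.frame with columns `wavelength`, `r`, in selection order.
#' @export
top_k_bands <- function(corr, k = 10) {
  if (k > length(corr$wavelengths)) stop("k exceeds the number of bands")
  o <- order(-abs(corr$r), corr$wavelengths)
  sel <- o[seq_len(k)]
  data.frame(wavelength = corr$wavelengths[sel], r = corr$r[sel])
}

#' Successive Projections Algorithm band selection
#'
#' Forward selection starting from band `k0`: at each iteration every
#' unselected column is replaced by its residual after orthogonal
#' projection onto the most recently selected (already-residualised)
#' column, and the column of largest residual norm is picked next. Because
#' candidates stay residualised across iterations, the loop performs
#' successive orthogonalisation, guaranteeing minimal collinearity among
#' the selected bands.
#'
#' @param X Samples-by-bands matrix.
#' @param k0 Start band (column index).
#' @param N Subset size, `<= min(samples, bands)`.
#' @param standardize Mean-centre and unit-scale columns first (default
#'   TRUE, the usual chemometrics convention).
#' @return Integer vector of `N` distinct column indices in selection
#'   order (first = `k0`).
#' @export
spa_select <- function(X, k0, N, standardize = TRUE) {
  stopifnot(k0 >= 1, k0 <= ncol(X))
  if (N > min(dim(X))) stop("N must not exceed min(samples, bands)")
  if (standardize) {
    X <- scale(X)
    X[, attr(X, "scaled:scale") == 0] <- 0
  }
  X <- unname(as.matrix(X))
  selected <- integer(N)
  selected[1] <- k0
  if (N == 1) return(selected)
  for (step in 2:N) {
    last <- X[, selected[step - 1]]
    denom <- sum(last^2)
    if (denom == 0) {
      stop("selected column has zero norm at iteration ", step - 1,
           " (degenerate input)")
    }
    # residualise all columns against the last pick; selected ones become 0
    proj <- as.numeric(crossprod(X, last)) / denom
    X <- X - outer(last, proj)
    norms <- colSums(X^2)
    norms[selected[seq_len(step - 1)]] <- -1
    selected[step] <- which.max(norms)
    if (norms[selected[step]] <= 0) {
      stop("all remaining columns have zero residual norm at iteration ",
           step, " (degenerate input)")
    }
  }
  selected
}

#' SPA with RMSECV-driven choice of start band and subset size
#'
#' Sweeps every start band `k0` and every subset size `N` in `2..N_max`;
#' for each candidate selection an ordinary least squares model of `y` on
#' the selected bands is scored by K-fold cross-validated RMSE (RMSECV),
#' and the selection minimising RMSECV is returned (ties: smaller `N`,
#' then smaller `k0`). Exploits the nesting of SPA's forward path: one
#' `spa_select` run to `N_max` yields the selections for every smaller
#' `N` as prefixes.
#'
#' @param X Samples-by-bands matrix.
#' @param y Indicator values.
#' @param N_max Largest subset size (default 10).
#' @param cv_folds Number of CV folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param k0_set Candidate start bands (default: all bands).
#' @param standardize Passed to [spa_select()].
#' @return `spa_result`: list with `selected` (column indices), `k0`,
#'   `N`, `rmsecv`, `path` (per-iteration residual norms of the winning
#'   run).
#' @export
spa_optimize <- function(X, y, N_max = 10, cv_folds = 5, seed = 1,
                         k0_set = seq_len(ncol(X)), standardize = TRUE) {
  n <- nrow(X)
  if (N_max > min(n - 1, ncol(X))) stop("N_max too large for this matrix")
  if (stats::sd(y) == 0) stop("constant indicator")
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  best <- list(rmsecv = Inf, N = Inf, k0 = Inf)
  for (k0 in k0_set) {
    sel_full <- tryCatch(spa_select(X, k0, N_max, standardize = standardize),
                         error = function(e) NULL)
    if (is.null(sel_full)) next
    for (N in 2:N_max) {
      sel <- sel_full[seq_len(N)]
      rmsecv <- .cv_rmse_ols(X[, sel, drop = FALSE], y, folds)
      if (rmsecv < best$rmsecv - 1e-12 ||
          (abs(rmsecv - best$rmsecv) <= 1e-12 &&
           (N < best$N || (N == best$N && k0 < best$k0)))) {
        best <- list(rmsecv = rmsecv, N = N, k0 = k0, selected = sel)
      }
    }
  }
  if (is.infinite(best$rmsecv)) stop("SPA failed for every candidate start band")
  path <- .spa_path(X, best$k0, best$N, standardize)
  structure(list(selected = best$selected, k0 = best$k0, N = best$N,
                 rmsecv = best$rmsecv, path = path),
            class = "spa_result")
}

# K-fold CV RMSE of OLS y ~ X; ridge fallback on rank deficiency
.cv_rmse_ols <- function(X, y, folds) {
  err2 <- 0
  for (f in unique(folds)) {
    tr <- folds != f
    Xtr <- cbind(1, X[tr, , drop = FALSE])
    Xte <- cbind(1, X[!tr, , drop = FALSE])
    beta <- tryCatch({
      qr.coef(qr(Xtr), y[tr])
    }, error = function(e) NULL)
    if (is.null(beta) || anyNA(beta)) {
      XtX <- crossprod(Xtr) + diag(1e-8, ncol(Xtr))
      beta <- solve(XtX, crossprod(Xtr, y[tr]))
    }
    err2 <- err2 + sum((y[!tr] - Xte %*% beta)^2)
  }
  sqrt(err2 / length(y))
}

# residual norm of each successive pick (diagnostic path)
.spa_path <- function(X, k0, N, standardize) {
  if (standardize) {
    X <- scale(X)
    X[, attr(X, "scaled:scale") == 0] <- 0
  }
  X <- unname(as.matrix(X))
  sel <- k0
  path <- sqrt(sum(X[, k0]^2))
  for (step in seq_len(N - 1)) {
    last <- X[, sel[length(sel)]]
    proj <- as.numeric(crossprod(X, last)) / sum(last^2)
    X <- X - outer(last, proj)
    norms <- colSums(X^2)
    norms[sel] <- -1
    nxt <- which.max(norms)
    sel <- c(sel, nxt)
    path <- c(path, sqrt(norms[nxt]))
  }
  path
}

#' @export
print.spa_result <- function(x, ...) {
  cat(sprintf("<SPA: N = %d, start band %d, RMSECV = %.4g; bands: %s>\n",
              x$N, x$k0, x$rmsecv, paste(x$selected, collapse = ", ")))
  invisible(x)
}
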
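#' Two-band vegetation index families
#'
#' `RVI = v1/v2`, `NDVI = (v1-v2)/(v1+v2)`, `DVI = v1-v2`; the
#' `FD`-prefixed variants apply the identical formulas to first-derivative
#' values.
#' @export
INDEX_KINDS <- c("RVI", "NDVI", "DVI", "FDRVI", "FDNDVI", "FDDVI")

#' Compute a two-band index
#'
#' @param v1,v2 Numeric vectors of band values (reflectance for
#'   RVI/NDVI/DVI, derivative reflectance for the FD variants).
#' @param kind One of [INDEX_KINDS].
#' @return Numeric vector; `NA` where the denominator is zero
#'   (undefined).
#' @export
two_band_index <- function(v1, v2, kind) {
  kind <- match.arg(kind, INDEX_KINDS)
  base <- sub("^FD", "", kind)
  switch(base,
         RVI = ifelse(v2 == 0, NA_real_, v1 / v2),
         NDVI = ifelse(v1 + v2 == 0, NA_real_, (v1 - v2) / (v1 + v2)),
         DVI = v1 - v2)
}

#' Exhaustive two-band index optimisation against an indicator
#'
#' Evaluates the Pearson correlation between the index and `y` for every
#' ordered band pair `(lambda1, lambda2)`, `lambda1 != lambda2`, and
#' returns the pair maximising `|r|`. Ordered pairs are searched (the
#' difference and ratio families are not symmetric); ties break toward the
#' smaller `lambda1`, then smaller `lambda2`. Pairs whose index is
#' undefined (zero denominator) or degenerate (zero variance) for the
#' sample set are skipped and counted.
#'
#' @param X Samples-by-bands matrix (original or derivative values,
#'   matching `kind`).
#' @param wavelengths Band wavelengths (nm), `length(ncol(X))`.
#' @param y Indicator values, one per sample, non-constant.
#' @param kind One of [INDEX_KINDS].
#' @param stride Evaluate every `stride`-th band only (1 = full grid).
#' @return `band_pair_result`: list with `index_kind`, `lambda1`,
#'   `lambda2`, `r`, `n`, `n_skipped`.
#' @export
optimize_band_pair <- function(X, wavelengths, y, kind, stride = 1) {
  kind <- match.arg(kind, INDEX_KINDS)
  stopifnot(ncol(X) == length(wavelengths), nrow(X) == length(y))
  if (nrow(X) < 3) stop("need at least 3 samples")
  if (stats::sd(y) == 0) stop("constant indicator: correlation undefined")
  keep <- seq(1, ncol(X), by = stride)
  Xs <- X[, keep, drop = FALSE]
  wl <- wavelengths[keep]
  B <- ncol(Xs)
  n <- nrow(Xs)
  yc <- y - mean(y)
  ynorm <- sqrt(sum(yc^2))
  base <- sub("^FD", "", kind)

  best_r <- 0
  best <- NULL
  n_skipped <- 0L
  for (i in seq_len(B)) {
    v1 <- Xs[, i]
    I <- switch(base,
                RVI = v1 / Xs,
                NDVI = (v1 - Xs) / (v1 + Xs),
                DVI = v1 - Xs)
    bad <- if (base == "RVI") {
      colSums(Xs == 0) > 0
    } else if (base == "NDVI") {
      colSums(v1 + Xs == 0) > 0
    } else rep(FALSE, B)
    cm <- colMeans(I)
    Ic <- I - rep(cm, each = n)
    ss <- colSums(Ic^2)
    num <- as.numeric(crossprod(yc, Ic))
    r <- num / (sqrt(ss) * ynorm)
    r[ss == 0] <- NA
    r[bad] <- NA
    r[i] <- NA                      # lambda1 == lambda2 excluded
    n_skipped <- n_skipped + sum(bad[-i])
    ok <- which(is.finite(r))
    if (length(ok)) {
      jbest <- ok[which.max(abs(r[ok]))]
      if (abs(r[jbest]) > best_r) {
        best_r <- abs(r[jbest])
        best <- list(i = i, j = jbest, r = r[jbest])
      }
    }
  }
  if (is.null(best)) stop("all band pairs skipped (undefined or degenerate index)")
  structure(list(index_kind = kind, lambda1 = wl[best$i],
                 lambda2 = wl[best$j], r = best$r, n = n,
                 n_skipped = n_skipped),
            class = "band_pair_result")
}

#' @export
print.band_pair_result <- function(x, ...) {
  cat(sprintf("<%s(%g, %g): r = %.3f, n = %d>\n",
              x$index_kind, x$lambda1, x$lambda2, x$r, x$n))
  invisible(x)
}

#' Evaluate a fitted band pair on a spectra matrix
#'
#' @param X Samples-by-bands matrix matching the pair's spectral kind.
#' @param wavelengths Band wavelengths of `X`.
#' @param pair A `band_pair_result`.
#' @return Numeric vector of index values, one per sample.
#' @export
apply_band_pair <- function(X, wavelengths, pair) {
  i1 <- match(pair$lambda1, wavelengths)
  i2 <- match(pair$lambda2, wavelengths)
  if (is.na(i1) || is.na(i2)) stop("pair wavelengths not on this grid")
  two_band_index(X[, i1], X[, i2], pair$index_kind)
}
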
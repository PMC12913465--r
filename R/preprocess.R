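#' The canonical 1-nm wavelength grid, 350-1350 nm
#' @return Integer vector 350:1350 (1001 bands).
#' @export
canonical_grid <- function() 350:1350

#' Resample a spectrum onto a target grid
#'
#' Duplicated input wavelengths are first collapsed to their mean
#' (de-duplication step of the preprocessing chain), then values are
#' linearly interpolated onto `grid`. Grid points coinciding with input
#' wavelengths pass through exactly. No extrapolation: the grid must lie
#' within the spectrum's span.
#'
#' @param spectrum_obj A [spectrum] (its `wavelengths` need not be unique
#'   or sorted strictly if duplicates carry equal-mean collapse).
#' @param grid Ascending numeric target grid in nm.
#' @return A [spectrum] on `grid`.
#' @export
resample_to_grid <- function(spectrum_obj, grid) {
  wl <- spectrum_obj$wavelengths
  v <- spectrum_obj$values
  if (any(duplicated(wl))) {
    agg <- tapply(v, wl, mean)
    wl <- as.numeric(names(agg))
    v <- as.numeric(agg)
    o <- order(wl)
    wl <- wl[o]; v <- v[o]
  }
  if (min(grid) < min(wl) || max(grid) > max(wl)) {
    stop("grid extends beyond the spectrum's wavelength span; no extrapolation")
  }
  out <- stats::approx(wl, v, xout = grid, method = "linear", ties = "mean")
  spectrum(grid, out$y, kind = spectrum_obj$kind,
           metadata = spectrum_obj$metadata)
}

# uniform-grid check shared by the convolution operators
.assert_uniform <- function(wl, what) {
  if (length(wl) < 3) stop(what, " needs at least 3 bands")
  h <- diff(wl)
  if (max(h) - min(h) > 1e-8 * mean(h)) {
    stop(what, " requires a uniform grid; resample first")
  }
  mean(h)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial convolution on a uniform grid. End bands
#' use the asymmetric rows of the Savitzky-Golay projection matrix, i.e. a
#' polynomial fitted over the edge window and evaluated off-centre, so
#' polynomials of degree `<= polyorder` are reproduced exactly everywhere.
#'
#' @param spectrum_obj A [spectrum] on a uniform grid.
#' @param window Odd window length in bands (default 11).
#' @param polyorder Polynomial order, `< window` (default 2).
#' @return Smoothed [spectrum], same kind.
#' @export
savgol_smooth <- function(spectrum_obj, window = 11, polyorder = 2) {
  if (window %% 2 != 1) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be smaller than window")
  .assert_uniform(spectrum_obj$wavelengths, "Savitzky-Golay smoothing")
  sm <- signal::sgolayfilt(spectrum_obj$values, p = polyorder, n = window)
  # clip tiny negative overshoot so the reflectance invariant survives
  if (spectrum_obj$kind == "reflectance") sm <- pmin(pmax(sm, 0), 1.5)
  spectrum(spectrum_obj$wavelengths, sm, kind = spectrum_obj$kind,
           metadata = spectrum_obj$metadata)
}

#' First-derivative reflectance (FDR)
#'
#' Canonical convention: central differences
#' `(R(l+h) - R(l-h)) / (2h)` on interior bands, one-sided differences at
#' the two ends. A Savitzky-Golay derivative is available via
#' `method = "savgol"`.
#'
#' @param spectrum_obj A reflectance [spectrum] on a uniform grid.
#' @param method `"central"` (default) or `"savgol"`.
#' @param window,polyorder Savitzky-Golay settings when
#'   `method = "savgol"`.
#' @return A [spectrum] of kind `"first_derivative"`, units per nm.
#' @export
first_derivative <- function(spectrum_obj, method = c("central", "savgol"),
                             window = 11, polyorder = 2) {
  method <- match.arg(method)
  if (spectrum_obj$kind != "reflectance") {
    stop("first_derivative expects a reflectance spectrum")
  }
  h <- .assert_uniform(spectrum_obj$wavelengths, "first_derivative")
  v <- spectrum_obj$values
  n <- length(v)
  if (method == "central") {
    d <- numeric(n)
    d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * h)
    d[1] <- (v[2] - v[1]) / h
    d[n] <- (v[n] - v[n - 1]) / h
  } else {
    d <- signal::sgolayfilt(v, p = polyorder, n = window, m = 1) / h
  }
  spectrum(spectrum_obj$wavelengths, d, kind = "first_derivative",
           metadata = spectrum_obj$metadata)
}

#' Standard preprocessing chain for one spectrum
#'
#' De-duplicate, resample to the canonical grid, Savitzky-Golay smooth;
#' optionally append the first derivative.
#'
#' @param spectrum_obj Raw reflectance [spectrum].
#' @param grid Target grid (default [canonical_grid()]).
#' @param window,polyorder Smoothing settings.
#' @param derivative If `TRUE` return `list(reflectance=, derivative=)`,
#'   else the smoothed spectrum only.
#' @export
preprocess_spectrum <- function(spectrum_obj, grid = canonical_grid(),
                                window = 11, polyorder = 2,
                                derivative = FALSE) {
  sm <- savgol_smooth(resample_to_grid(spectrum_obj, grid),
                      window = window, polyorder = polyorder)
  if (!derivative) return(sm)
  list(reflectance = sm, derivative = first_derivative(sm))
}

#' Derivative transform of a whole sample table
#'
#' @param table A reflectance [sample_table].
#' @param method Passed to [first_derivative()].
#' @return A [sample_table] of kind `"first_derivative"` on the same grid.
#' @export
derivative_table <- function(table, method = "central") {
  wl <- table$wavelengths
  h <- .assert_uniform(wl, "derivative_table")
  X <- table$spectra
  n <- ncol(X)
  D <- X
  D[, 2:(n - 1)] <- (X[, 3:n] - X[, 1:(n - 2)]) / (2 * h)
  D[, 1] <- (X[, 2] - X[, 1]) / h
  D[, n] <- (X[, n] - X[, n - 1]) / h
  if (method != "central") {
    D <- t(apply(X, 1, function(r) signal::sgolayfilt(r, p = 2, n = 11, m = 1) / h))
    dimnames(D) <- dimnames(X)
  }
  sample_table(D, wl, table$physiology, kind = "first_derivative",
               metadata = table$metadata)
}
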
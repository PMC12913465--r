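#' Edge window definitions for trilateral parameter extraction
#'
#' The red edge window follows the field convention 680-780 nm; the blue
#' edge, yellow edge, green peak and red valley windows are the prevailing
#' literature conventions and are overridable.
#'
#' @param red_edge,blue_edge,yellow_edge,green_peak,red_valley Two-element
#'   nm intervals.
#' @return An object of class `edge_windows`.
#' @export
edge_windows <- function(red_edge = c(680, 780), blue_edge = c(490, 530),
                         yellow_edge = c(560, 640),
                         green_peak = c(510, 560),
                         red_valley = c(640, 700)) {
  w <- list(red_edge = red_edge, blue_edge = blue_edge,
            yellow_edge = yellow_edge, green_peak = green_peak,
            red_valley = red_valley)
  for (nm in names(w)) {
    iv <- w[[nm]]
    if (length(iv) != 2 || iv[1] >= iv[2]) stop("invalid interval for ", nm)
  }
  structure(w, class = "edge_windows")
}

#' Names of the 20 trilateral parameters
#' @export
TRILATERAL_NAMES <- c("Dr", "lambda_r", "Db", "lambda_b", "Dy", "lambda_y",
                      "Rg", "lambda_g", "Rr", "lambda_v",
                      "SDr", "SDb", "SDy",
                      "Rg_minus_Rr_norm", "Rg_over_Rr",
                      "SDr_over_SDb", "SDr_over_SDy",
                      "SDr_minus_SDb", "SDr_minus_SDb_norm",
                      "SDr_minus_SDy_norm")

.window_idx <- function(wl, interval) {
  idx <- which(wl >= interval[1] & wl <= interval[2])
  if (length(idx) < 2) stop("window [", interval[1], ", ", interval[2],
                            "] nm covers fewer than 2 grid points")
  idx
}

.trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# ratio/normalised indices with 0-denominator flagged as NA
.safe_div <- function(a, b) if (b == 0) NA_real_ else a / b

#' Extract the 20 trilateral (three-edge) spectral parameters
#'
#' Positional and amplitude parameters: `Dr` = maximum first-derivative
#' reflectance (FDR) over the red edge and `lambda_r` its wavelength (the
#' red-edge position); `Db`/`lambda_b` likewise on the blue edge;
#' `Dy`/`lambda_y` the FDR value of largest magnitude over the yellow edge
#' (sign retained — the derivative is typically negative there);
#' `Rg`/`lambda_g` the green-peak reflectance maximum; `Rr`/`lambda_v` the
#' red-valley reflectance minimum. Area parameters: `SDr`, `SDb` are
#' trapezoidal integrals of the signed FDR over their windows; `SDy`
#' integrates `|FDR|` so that all areas are positive and the printed
#' ratios stay well-defined. The seven combination indices are
#' `(Rg-Rr)/(Rg+Rr)`, `Rg/Rr`, `SDr/SDb`, `SDr/SDy`, `SDr-SDb`,
#' `(SDr-SDb)/(SDr+SDb)` and `(SDr-SDy)/(SDr+SDy)`; ratio fields are `NA`
#' when the denominator is zero. Argmax/argmin ties break toward the
#' shorter wavelength.
#'
#' @param reflectance Reflectance [spectrum].
#' @param derivative Matching first-derivative [spectrum] on the same
#'   grid.
#' @param windows An [edge_windows] object.
#' @return Named numeric vector over [TRILATERAL_NAMES] (class
#'   `trilateral_parameters`).
#' @export
extract_trilateral <- function(reflectance, derivative,
                               windows = edge_windows()) {
  wl <- reflectance$wavelengths
  if (length(derivative$wavelengths) != length(wl) ||
      any(derivative$wavelengths != wl)) {
    stop("reflectance and derivative must share one grid")
  }
  R <- reflectance$values
  D <- derivative$values

  ire <- .window_idx(wl, windows$red_edge)
  ibe <- .window_idx(wl, windows$blue_edge)
  iye <- .window_idx(wl, windows$yellow_edge)
  igp <- .window_idx(wl, windows$green_peak)
  irv <- .window_idx(wl, windows$red_valley)

  j <- ire[which.max(D[ire])]
  Dr <- D[j]; lambda_r <- wl[j]
  j <- ibe[which.max(D[ibe])]
  Db <- D[j]; lambda_b <- wl[j]
  j <- iye[which.max(abs(D[iye]))]
  Dy <- D[j]; lambda_y <- wl[j]
  j <- igp[which.max(R[igp])]
  Rg <- R[j]; lambda_g <- wl[j]
  j <- irv[which.min(R[irv])]
  Rr <- R[j]; lambda_v <- wl[j]

  SDr <- .trapz(wl[ire], D[ire])
  SDb <- .trapz(wl[ibe], D[ibe])
  SDy <- .trapz(wl[iye], abs(D[iye]))

  out <- c(Dr = Dr, lambda_r = lambda_r, Db = Db, lambda_b = lambda_b,
           Dy = Dy, lambda_y = lambda_y, Rg = Rg, lambda_g = lambda_g,
           Rr = Rr, lambda_v = lambda_v, SDr = SDr, SDb = SDb, SDy = SDy,
           Rg_minus_Rr_norm = .safe_div(Rg - Rr, Rg + Rr),
           Rg_over_Rr = .safe_div(Rg, Rr),
           SDr_over_SDb = .safe_div(SDr, SDb),
           SDr_over_SDy = .safe_div(SDr, SDy),
           SDr_minus_SDb = SDr - SDb,
           SDr_minus_SDb_norm = .safe_div(SDr - SDb, SDr + SDb),
           SDr_minus_SDy_norm = .safe_div(SDr - SDy, SDr + SDy))
  structure(out, class = c("trilateral_parameters", "numeric"))
}

#' Red-edge summary: position, amplitude, area
#'
#' Convenience projection of [extract_trilateral()] needing only the
#' derivative spectrum.
#'
#' @param derivative First-derivative [spectrum].
#' @param window Red-edge nm interval (default `c(680, 780)`).
#' @return Named vector `lambda_r`, `Dr`, `SDr`.
#' @export
red_edge_summary <- function(derivative, window = c(680, 780)) {
  wl <- derivative$wavelengths
  idx <- .window_idx(wl, window)
  D <- derivative$values
  j <- idx[which.max(D[idx])]
  c(lambda_r = wl[j], Dr = D[j], SDr = .trapz(wl[idx], D[idx]))
}

#' Trilateral parameters for every sample of a table
#'
#' @param table Reflectance [sample_table].
#' @param windows An [edge_windows].
#' @param derivative Optional pre-computed derivative [sample_table]; by
#'   default the central-difference derivative is used.
#' @return Samples-by-20 matrix of trilateral parameters (rows = sample
#'   ids).
#' @export
trilateral_table <- function(table, windows = edge_windows(),
                             derivative = NULL) {
  if (is.null(derivative)) derivative <- derivative_table(table)
  wl <- table$wavelengths
  out <- t(vapply(seq_len(nrow(table$spectra)), function(i) {
    as.numeric(extract_trilateral(
      spectrum(wl, table$spectra[i, ], kind = "reflectance"),
      spectrum(wl, derivative$spectra[i, ], kind = "first_derivative"),
      windows))
  }, numeric(length(TRILATERAL_NAMES))))
  dimnames(out) <- list(rownames(table$spectra), TRILATERAL_NAMES)
  out
}
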
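#' Physiological indicator names handled by the pipeline
#'
#' The seven canopy physiological indicators: relative chlorophyll content
#' (`SPAD`, unitless), net photosynthetic rate (`A`, umol m-2 s-1), stomatal
#' conductance to water vapour (`gsw`, mol m-2 s-1), intercellular CO2
#' concentration (`Ci`, umol mol-1), effective PSII quantum yield in the
#' light (`FvpFmp`, i.e. Fv'/Fm', unitless in \[0,1\]), photochemical
#' quenching (`qP`) and non-photochemical quenching (`qN`).
#'
#' @format Character vector of length 7.
#' @export
INDICATORS <- c("SPAD", "A", "gsw", "Ci", "FvpFmp", "qP", "qN")

#' Metadata keys carried with each spectrum
#' @keywords internal
META_KEYS <- c("sample_id", "group", "stage", "date", "pot", "replicate")

#' Construct a spectrum
#'
#' A spectrum is one sample's wavelength grid plus reflectance (or
#' first-derivative reflectance) values, with per-sample metadata.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param values Numeric vector of the same length. Reflectance spectra are
#'   unitless fractions and must lie within \[0, 1.5\] (tolerating slight
#'   white-reference calibration overshoot); derivative spectra are per nm
#'   and unconstrained.
#' @param kind `"reflectance"` or `"first_derivative"`.
#' @param metadata Named list; recognised keys are `sample_id`, `group`
#'   (`"CK"` control / `"T"` treatment), `stage`, `date`, `pot`,
#'   `replicate`.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelengths, values,
                     kind = c("reflectance", "first_derivative"),
                     metadata = list()) {
  kind <- match.arg(kind)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values)) {
    stop("wavelengths and values must have equal length")
  }
  if (length(wavelengths) >= 2 && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (anyNA(wavelengths) || anyNA(values)) {
    stop("NA values are not allowed in a spectrum")
  }
  if (kind == "reflectance" && (any(values < 0) || any(values > 1.5))) {
    stop("reflectance values must lie within [0, 1.5]")
  }
  structure(
    list(wavelengths = wavelengths, values = values, kind = kind,
         metadata = metadata),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d bands, %g-%g nm%s>\n",
              x$kind, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths),
              if (!is.null(x$metadata$sample_id)) {
                paste0(", id=", x$metadata$sample_id)
              } else ""))
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$wavelengths)

#' Stack spectra sharing one grid into a samples-by-bands matrix
#'
#' @param spectra List of `spectrum` objects on an identical grid.
#' @return Numeric matrix, one row per spectrum; row names are sample ids
#'   (when present), column names the wavelengths.
#' @export
spectra_matrix <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  grid <- spectra[[1]]$wavelengths
  for (s in spectra) {
    if (length(s$wavelengths) != length(grid) ||
        any(s$wavelengths != grid)) {
      stop("all spectra must share an identical wavelength grid")
    }
  }
  m <- do.call(rbind, lapply(spectra, function(s) s$values))
  ids <- vapply(seq_along(spectra), function(i) {
    id <- spectra[[i]]$metadata$sample_id
    if (is.null(id)) paste0("s", i) else as.character(id)
  }, character(1))
  dimnames(m) <- list(ids, as.character(grid))
  m
}

#' Metadata of a spectra list as a data frame
#' @param spectra List of `spectrum` objects.
#' @return data.frame with one row per spectrum and the standard metadata
#'   columns (missing keys become `NA`).
#' @export
spectra_metadata <- function(spectra) {
  rows <- lapply(spectra, function(s) {
    md <- s$metadata
    vals <- lapply(META_KEYS, function(k) {
      if (is.null(md[[k]])) NA else md[[k]]
    })
    names(vals) <- META_KEYS
    as.data.frame(vals, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Construct an aligned sample table
#'
#' Couples a spectra matrix (samples x bands on one grid) with a physiology
#' table keyed by the same sample ids, the unit on which band selection and
#' model fitting operate.
#'
#' @param spectra Samples-by-bands numeric matrix with sample ids as row
#'   names.
#' @param wavelengths Numeric grid matching `ncol(spectra)`.
#' @param physiology data.frame with a `sample_id` column and indicator
#'   columns (any subset of [INDICATORS]), same ids and order as
#'   `rownames(spectra)`.
#' @param kind Spectral kind of the matrix.
#' @param metadata Optional per-sample metadata data.frame (same order).
#' @return An object of class `sample_table`.
#' @export
sample_table <- function(spectra, wavelengths, physiology,
                         kind = "reflectance", metadata = NULL) {
  stopifnot(is.matrix(spectra), ncol(spectra) == length(wavelengths))
  if (is.null(rownames(spectra))) {
    stop("spectra matrix must carry sample ids as row names")
  }
  if (!"sample_id" %in% names(physiology)) {
    stop("physiology table must have a sample_id column")
  }
  if (!identical(as.character(physiology$sample_id), rownames(spectra))) {
    stop("physiology sample ids must match spectra row names in order")
  }
  structure(
    list(spectra = spectra, wavelengths = as.numeric(wavelengths),
         physiology = physiology, kind = kind, metadata = metadata),
    class = "sample_table"
  )
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table: %d samples x %d bands (%s), indicators: %s>\n",
              nrow(x$spectra), ncol(x$spectra), x$kind,
              paste(intersect(INDICATORS, names(x$physiology)),
                    collapse = ", ")))
  invisible(x)
}

#' Subset a sample table by row index or metadata predicate
#' @param table A `sample_table`.
#' @param idx Integer or logical index over samples.
#' @return A `sample_table` restricted to the selected samples.
#' @export
subset_samples <- function(table, idx) {
  sample_table(table$spectra[idx, , drop = FALSE], table$wavelengths,
               table$physiology[idx, , drop = FALSE], kind = table$kind,
               metadata = if (!is.null(table$metadata)) {
                 table$metadata[idx, , drop = FALSE]
               } else NULL)
}
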
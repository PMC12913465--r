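#' Read a spectra table from CSV
#'
#' Two plain-text dialects are supported. `wide_csv`: first column
#' `wavelength`, one column per sample with the sample id in the header; an
#' optional metadata preamble of rows whose first cell is `!group`,
#' `!stage`, `!date`, `!pot` or `!replicate` carries per-sample metadata.
#' `long_csv`: columns `sample_id, wavelength, value` plus optional
#' companion metadata columns (`group`, `stage`, `date`, `pot`,
#' `replicate`, `kind`).
#'
#' @param source Path or connection to a CSV file.
#' @param dialect `"wide_csv"` or `"long_csv"`.
#' @param kind Spectral kind to stamp on the parsed spectra (ignored for
#'   long tables that carry a `kind` column).
#' @param reflectance_scale `"fraction"` (canonical) or `"percent"`;
#'   percent input is divided by 100 on read.
#' @return List of [spectrum] objects sharing one grid.
#' @export
read_spectra_table <- function(source, dialect = c("wide_csv", "long_csv"),
                               kind = "reflectance",
                               reflectance_scale = c("fraction", "percent")) {
  dialect <- match.arg(dialect)
  reflectance_scale <- match.arg(reflectance_scale)
  raw <- utils::read.csv(source, check.names = FALSE,
                         colClasses = "character")
  rescale <- function(v) if (reflectance_scale == "percent") v / 100 else v

  if (dialect == "wide_csv") {
    if (ncol(raw) < 2) stop("wide table needs a wavelength column plus at least one sample column")
    is_meta <- startsWith(raw[[1]], "!")
    meta_rows <- raw[is_meta, , drop = FALSE]
    dat <- raw[!is_meta, , drop = FALSE]
    wl <- as.numeric(dat[[1]])
    if (anyNA(wl)) stop("non-numeric wavelength entries in wide table")
    if (any(duplicated(wl))) stop("duplicate wavelengths in wide table")
    if (any(diff(wl) <= 0)) stop("wavelengths must be strictly increasing")
    ids <- names(raw)[-1]
    lapply(seq_along(ids), function(j) {
      md <- list(sample_id = ids[j])
      if (nrow(meta_rows)) {
        for (r in seq_len(nrow(meta_rows))) {
          key <- sub("^!", "", meta_rows[r, 1])
          md[[key]] <- meta_rows[r, j + 1]
        }
      }
      vals <- as.numeric(dat[[j + 1]])
      if (anyNA(vals)) stop("non-numeric reflectance entries in wide table")
      spectrum(wl, if (kind == "reflectance") rescale(vals) else vals,
               kind = kind, metadata = md)
    })
  } else {
    need <- c("sample_id", "wavelength", "value")
    if (!all(need %in% names(raw))) {
      stop("long table needs columns sample_id, wavelength, value")
    }
    ids <- unique(raw$sample_id)
    grids <- NULL
    out <- lapply(ids, function(id) {
      sub <- raw[raw$sample_id == id, , drop = FALSE]
      wl <- as.numeric(sub$wavelength)
      if (any(duplicated(wl))) stop("duplicate wavelengths for sample ", id)
      o <- order(wl)
      k <- if ("kind" %in% names(sub)) sub$kind[1] else kind
      md <- list(sample_id = id)
      for (key in setdiff(META_KEYS, "sample_id")) {
        if (key %in% names(sub)) md[[key]] <- sub[[key]][1]
      }
      vals <- as.numeric(sub$value)[o]
      spectrum(wl[o], if (k == "reflectance") rescale(vals) else vals,
               kind = k, metadata = md)
    })
    grid <- out[[1]]$wavelengths
    for (s in out) {
      if (length(s$wavelengths) != length(grid) ||
          any(s$wavelengths != grid)) {
        stop("ragged wavelength grids across samples")
      }
    }
    out
  }
}

#' Write a spectra table to CSV
#'
#' Inverse of [read_spectra_table()]; `read(write(x))` is value-exact at
#' the emitted precision (default 8 significant digits; the exchange spec
#' guarantees 6).
#'
#' @param spectra List of [spectrum] objects sharing one grid and kind.
#' @param path Output file path.
#' @param dialect `"wide_csv"` or `"long_csv"`.
#' @param digits Significant digits to emit.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(spectra, path,
                                dialect = c("wide_csv", "long_csv"),
                                digits = 8) {
  dialect <- match.arg(dialect)
  fmt <- function(v) formatC(v, digits = digits, format = "g")
  if (length(spectra) == 0) {
    writeLines(if (dialect == "wide_csv") "wavelength"
               else "sample_id,wavelength,value", path)
    return(invisible(path))
  }
  kinds <- unique(vapply(spectra, function(s) s$kind, character(1)))
  if (length(kinds) > 1) stop("cannot mix reflectance and derivative spectra in one table")
  grid <- spectra[[1]]$wavelengths
  for (s in spectra) {
    if (length(s$wavelengths) != length(grid) || any(s$wavelengths != grid)) {
      stop("all spectra must share one grid")
    }
  }
  md <- spectra_metadata(spectra)
  if (dialect == "wide_csv") {
    header <- paste(c("wavelength", md$sample_id), collapse = ",")
    meta_lines <- character(0)
    for (key in setdiff(META_KEYS, "sample_id")) {
      if (!all(is.na(md[[key]]))) {
        meta_lines <- c(meta_lines,
                        paste(c(paste0("!", key), md[[key]]), collapse = ","))
      }
    }
    vals <- vapply(spectra, function(s) fmt(s$values), character(length(grid)))
    body <- apply(cbind(format(grid, trim = TRUE), vals), 1, paste,
                  collapse = ",")
    writeLines(c(header, meta_lines, body), path)
  } else {
    rows <- lapply(seq_along(spectra), function(i) {
      s <- spectra[[i]]
      data.frame(sample_id = md$sample_id[i], wavelength = grid,
                 value = fmt(s$values), group = md$group[i],
                 stage = md$stage[i], date = md$date[i], pot = md$pot[i],
                 replicate = md$replicate[i], kind = s$kind,
                 stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                     quote = FALSE, na = "")
  }
  invisible(path)
}

#' Read a physiology table
#'
#' Expects a CSV with a `sample_id` column and any subset of the seven
#' indicator columns ([INDICATORS]). Missing indicators are flagged in the
#' `"missing_indicators"` attribute, never imputed.
#'
#' @param source Path or connection.
#' @return data.frame with attribute `missing_indicators`.
#' @export
read_physiology_table <- function(source) {
  df <- utils::read.csv(source, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("physiology table needs a sample_id column")
  present <- intersect(INDICATORS, names(df))
  if (length(present) == 0) stop("no indicator columns found")
  for (ind in present) df[[ind]] <- as.numeric(df[[ind]])
  if ("SPAD" %in% present && any(df$SPAD < 0, na.rm = TRUE)) {
    stop("negative SPAD values are not physically admissible")
  }
  if ("FvpFmp" %in% present && any(df$FvpFmp > 1, na.rm = TRUE)) {
    stop("Fv'/Fm' cannot exceed 1")
  }
  attr(df, "missing_indicators") <- setdiff(INDICATORS, present)
  df
}

#' Write a physiology table
#' @param physiology data.frame with `sample_id` and indicator columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_physiology_table <- function(physiology, path) {
  utils::write.csv(physiology, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average replicate scans
#'
#' Per-wavelength arithmetic mean over groups of spectra sharing the given
#' metadata keys (field protocol: several scans per sample, the mean is
#' recorded). The `replicate` field is cleared on the averaged output.
#'
#' @param spectra List of [spectrum] objects on one grid and kind.
#' @param by Metadata keys defining replicate groups (default
#'   `"sample_id"`).
#' @return List of averaged [spectrum] objects, one per group, in order of
#'   first appearance.
#' @export
average_replicates <- function(spectra, by = "sample_id") {
  if (length(spectra) == 0) stop("empty spectra list")
  md <- spectra_metadata(spectra)
  key <- do.call(paste, c(md[by], sep = "\r"))
  groups <- unique(key)
  grid <- spectra[[1]]$wavelengths
  kind <- spectra[[1]]$kind
  lapply(groups, function(g) {
    members <- spectra[key == g]
    for (s in members) {
      if (length(s$wavelengths) != length(grid) ||
          any(s$wavelengths != grid) || s$kind != kind) {
        stop("replicates must share one grid and kind")
      }
    }
    m <- do.call(rbind, lapply(members, function(s) s$values))
    md_new <- members[[1]]$metadata
    md_new$replicate <- NULL
    spectrum(grid, colMeans(m), kind = kind, metadata = md_new)
  })
}

#' Align spectra with a physiology table into a sample table
#'
#' Intersects sample ids; ids present on only one side are dropped and
#' reported in the `"dropped_ids"` attribute. Errors when the
#' intersection is empty.
#'
#' @param spectra List of [spectrum] objects on one grid, or a
#'   samples-by-bands matrix with ids as row names (then `wavelengths`
#'   must be given).
#' @param physiology data.frame with `sample_id` and indicator columns.
#' @param wavelengths Grid, required when `spectra` is a matrix.
#' @return A [sample_table] with attribute `dropped_ids`.
#' @export
validate_alignment <- function(spectra, physiology, wavelengths = NULL) {
  if (is.list(spectra) && !is.matrix(spectra)) {
    mat <- spectra_matrix(spectra)
    wavelengths <- spectra[[1]]$wavelengths
    kind <- spectra[[1]]$kind
    meta <- spectra_metadata(spectra)
  } else {
    mat <- spectra
    kind <- "reflectance"
    meta <- NULL
    if (is.null(wavelengths)) stop("wavelengths required with a matrix input")
  }
  ids_s <- rownames(mat)
  ids_p <- as.character(physiology$sample_id)
  keep <- intersect(ids_s, ids_p)
  if (length(keep) == 0) stop("no common sample ids between spectra and physiology")
  dropped <- union(setdiff(ids_s, keep), setdiff(ids_p, keep))
  mat <- mat[match(keep, ids_s), , drop = FALSE]
  phys <- physiology[match(keep, ids_p), , drop = FALSE]
  if (!is.null(meta)) meta <- meta[match(keep, meta$sample_id), , drop = FALSE]
  out <- sample_table(mat, wavelengths, phys, kind = kind, metadata = meta)
  attr(out, "dropped_ids") <- dropped
  out
}
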
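#' Pipeline configuration
#'
#' Collects every tunable of the stage-wise analysis with its default.
#'
#' @param indicators Named list mapping stage to the indicators analysed
#'   there; the default pairs SPAD with the stage's most stress-sensitive
#'   gas-exchange and fluorescence parameters (branching/flowering: gsw,
#'   qP; budding: A, qN).
#' @param models Model kinds to fit.
#' @param feature_sets Feature sets to assemble (see
#'   [build_features()]).
#' @param stride Band stride of the exhaustive two-band pair search
#'   (1 = full 1-nm grid).
#' @param spa_stride Band stride of the SPA start-band sweep; SPA's full
#'   `k0` sweep is quadratic in bands, so a stride of 10 on the 1-nm grid
#'   keeps it tractable while still covering the whole range.
#' @param spa_nmax Largest SPA subset size.
#' @param cv_folds CV folds for SPA RMSECV and internal model tuning.
#' @param tp_threshold `|r|` cut for the trilateral-parameter (TP)
#'   feature set (default 0.6).
#' @param window,polyorder Savitzky-Golay settings.
#' @param test_fraction Held-out fraction of the 3:1 split.
#' @param seed Master seed: split, selector CV and model seeds derive
#'   from it.
#' @param selector_scope `"train"` (default) fits all selectors on the
#'   training partition only, avoiding leakage into the test set;
#'   `"all"` fits them on every sample of a group, comparable to
#'   published tables built without a held-out partition.
#' @param windows [edge_windows()] for trilateral extraction.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(indicators = list(branching = c("SPAD", "gsw", "qP"),
                                              budding = c("SPAD", "A", "qN"),
                                              flowering = c("SPAD", "gsw", "qP")),
                            models = c("SVR", "RFR", "PLSR"),
                            feature_sets = c("OS1", "OS2", "FDS1", "FDS2",
                                             "TP", "NDVI", "FDNDVI"),
                            stride = 1, spa_stride = 10, spa_nmax = 10,
                            cv_folds = 5, tp_threshold = 0.6,
                            window = 11, polyorder = 2,
                            test_fraction = 0.25, seed = 1,
                            selector_scope = c("train", "all"),
                            windows = edge_windows()) {
  structure(list(indicators = indicators, models = models,
                 feature_sets = feature_sets, stride = stride,
                 spa_stride = spa_stride, spa_nmax = spa_nmax,
                 cv_folds = cv_folds, tp_threshold = tp_threshold,
                 window = window, polyorder = polyorder,
                 test_fraction = test_fraction, seed = seed,
                 selector_scope = match.arg(selector_scope),
                 windows = windows),
            class = "pipeline_config")
}

#' Fit the feature selectors for one group and indicator
#'
#' Top-10 correlation bands (OS1/FDS1), SPA-optimised bands (OS2/FDS2),
#' the trilateral parameters passing the `|r|` threshold (TP), and the
#' optimal NDVI/FDNDVI band pairs — all fitted on the rows given by
#' `fit_idx` (the training partition, unless `selector_scope = "all"`).
#'
#' @param refl,deriv Reflectance / derivative [sample_table]s on one
#'   grid.
#' @param tri Samples-by-20 trilateral matrix (see
#'   [trilateral_table()]).
#' @param indicator Indicator name.
#' @param fit_idx Row indices used for fitting.
#' @param config A [pipeline_config()].
#' @return List of fitted selectors.
#' @export
fit_selectors <- function(refl, deriv, tri, indicator, fit_idx, config) {
  wl <- refl$wavelengths
  y <- refl$physiology[[indicator]][fit_idx]
  Xo <- refl$spectra[fit_idx, , drop = FALSE]
  Xd <- deriv$spectra[fit_idx, , drop = FALSE]

  co <- correlation_spectrum(Xo, wl, y, indicator)
  cd <- correlation_spectrum(Xd, wl, y, indicator)
  os1 <- top_k_bands(co, 10)
  fds1 <- top_k_bands(cd, 10)

  keep <- seq(1, length(wl), by = config$spa_stride)
  spa_o <- spa_optimize(Xo[, keep, drop = FALSE], y, N_max = config$spa_nmax,
                        cv_folds = config$cv_folds, seed = config$seed)
  spa_d <- spa_optimize(Xd[, keep, drop = FALSE], y, N_max = config$spa_nmax,
                        cv_folds = config$cv_folds, seed = config$seed)

  tri_fit <- tri[fit_idx, , drop = FALSE]
  tri_r <- suppressWarnings(
    apply(tri_fit, 2, function(col) {
      if (anyNA(col) || stats::sd(col) == 0) return(NA_real_)
      stats::cor(col, y)
    }))
  tp_cols <- names(tri_r)[!is.na(tri_r) & abs(tri_r) > config$tp_threshold]

  ndvi <- optimize_band_pair(Xo, wl, y, "NDVI", stride = config$stride)
  fdndvi <- optimize_band_pair(Xd, wl, y, "FDNDVI", stride = config$stride)

  list(indicator = indicator,
       corr_original = co, corr_derivative = cd,
       os1 = os1$wavelength, fds1 = fds1$wavelength,
       os2 = wl[keep][spa_o$selected], fds2 = wl[keep][spa_d$selected],
       spa_original = spa_o, spa_derivative = spa_d,
       tp = tp_cols, tp_r = tri_r,
       ndvi = ndvi, fdndvi = fdndvi)
}

#' Assemble a design matrix for one feature set
#'
#' `OS1`/`FDS1`: the top-10 correlation bands of the original /
#' derivative spectra. `OS2`/`FDS2`: the SPA-selected bands. `TP`: the
#' trilateral parameters whose fitted `|r|` exceeded the threshold.
#' `NDVI`/`FDNDVI`: the single optimised two-band index value.
#'
#' @param feature_set One of the seven set names.
#' @param refl,deriv Reflectance / derivative [sample_table]s.
#' @param tri Trilateral matrix.
#' @param selectors Output of [fit_selectors()].
#' @param idx Row indices to assemble (default: all).
#' @return Numeric design matrix.
#' @export
build_features <- function(feature_set, refl, deriv, tri, selectors,
                           idx = seq_len(nrow(refl$spectra))) {
  wl <- refl$wavelengths
  pick <- function(tab, bands) tab[idx, match(bands, wl), drop = FALSE]
  switch(feature_set,
         OS1 = pick(refl$spectra, selectors$os1),
         FDS1 = pick(deriv$spectra, selectors$fds1),
         OS2 = pick(refl$spectra, selectors$os2),
         FDS2 = pick(deriv$spectra, selectors$fds2),
         TP = {
           if (length(selectors$tp) == 0) {
             stop("empty TP feature set: no trilateral parameter passed the ",
                  "|r| threshold; lower tp_threshold")
           }
           tri[idx, selectors$tp, drop = FALSE]
         },
         NDVI = matrix(apply_band_pair(refl$spectra[idx, , drop = FALSE],
                                       wl, selectors$ndvi), ncol = 1,
                       dimnames = list(NULL, "NDVI")),
         FDNDVI = matrix(apply_band_pair(deriv$spectra[idx, , drop = FALSE],
                                         wl, selectors$fdndvi), ncol = 1,
                         dimnames = list(NULL, "FDNDVI")),
         stop("unknown feature set: ", feature_set))
}

#' Savitzky-Golay smooth every spectrum of a sample table
#'
#' Row-wise [savgol_smooth()] over the whole spectra matrix.
#'
#' @param table A reflectance [sample_table] on a uniform grid.
#' @param window,polyorder Savitzky-Golay settings (defaults 11 / 2).
#' @return The smoothed [sample_table].
#' @export
smooth_table <- function(table, window = 11, polyorder = 2) {
  .assert_uniform(table$wavelengths, "Savitzky-Golay smoothing")
  sm <- t(apply(table$spectra, 1, signal::sgolayfilt, p = polyorder,
                n = window))
  sm <- pmin(pmax(sm, 0), 1.5)
  dimnames(sm) <- dimnames(table$spectra)
  sample_table(sm, table$wavelengths, table$physiology, kind = table$kind,
               metadata = table$metadata)
}

# internal alias kept for the pipeline call sites
.smooth_table <- smooth_table

#' Run the full analysis for one growth stage
#'
#' Preprocessing (Savitzky-Golay smoothing + first derivative),
#' trilateral extraction, per-group/indicator band selection
#' (correlation top-10 and SPA), two-band index optimisation for all six
#' families, feature-set assembly and the model x indicator x group x
#' feature-set fits. All randomness derives from `config$seed`.
#'
#' @param table Raw reflectance [sample_table] for one stage (groups CK
#'   and T in `physiology$group`).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every table is written
#'   as CSV.
#' @return `stage_report`: list with `stage`, `band_tables`,
#'   `index_tables`, `model_tables`, `best_features`, `red_edge`, `eta`.
#' @export
run_stage_analysis <- function(table, config = pipeline_config(),
                               out_dir = NULL) {
  stage <- table$physiology$stage[1]
  indicators <- config$indicators[[stage]]
  if (is.null(indicators)) indicators <- intersect(INDICATORS,
                                                   names(table$physiology))
  refl <- .smooth_table(table, config$window, config$polyorder)
  deriv <- derivative_table(refl)
  tri <- trilateral_table(refl, windows = config$windows,
                          derivative = deriv)
  groups <- unique(table$physiology$group)

  band_rows <- list(); index_rows <- list(); model_rows <- list()
  for (grp in groups) {
    gidx <- which(table$physiology$group == grp)
    g_refl <- subset_samples(refl, gidx)
    g_deriv <- subset_samples(deriv, gidx)
    g_tri <- tri[gidx, , drop = FALSE]
    n_g <- length(gidx)
    split <- split_train_test(n_g, config$test_fraction, seed = config$seed)
    fit_idx <- if (config$selector_scope == "all") seq_len(n_g) else split$train

    for (ind in indicators) {
      if (!ind %in% names(g_refl$physiology) ||
          anyNA(g_refl$physiology[[ind]])) {
        message("skipping ", ind, " in ", grp, ": indicator missing")
        next
      }
      sel <- fit_selectors(g_refl, g_deriv, g_tri, ind, fit_idx, config)
      y <- g_refl$physiology[[ind]]

      band_rows[[length(band_rows) + 1]] <- data.frame(
        stage = stage, group = grp, indicator = ind,
        method = c(rep("corr_top10_original", 10),
                   rep("corr_top10_derivative", 10),
                   rep("spa_original", length(sel$os2)),
                   rep("spa_derivative", length(sel$fds2))),
        wavelength = c(sel$os1, sel$fds1, sel$os2, sel$fds2),
        stringsAsFactors = FALSE)

      for (kind in c("RVI", "NDVI", "DVI")) {
        pr <- optimize_band_pair(g_refl$spectra[fit_idx, , drop = FALSE],
                                 refl$wavelengths, y[fit_idx], kind,
                                 stride = config$stride)
        index_rows[[length(index_rows) + 1]] <- data.frame(
          stage = stage, group = grp, indicator = ind, index_kind = kind,
          lambda1 = pr$lambda1, lambda2 = pr$lambda2, r = pr$r, n = pr$n,
          stringsAsFactors = FALSE)
      }
      for (kind in c("FDRVI", "FDNDVI", "FDDVI")) {
        pr <- optimize_band_pair(g_deriv$spectra[fit_idx, , drop = FALSE],
                                 refl$wavelengths, y[fit_idx], kind,
                                 stride = config$stride)
        index_rows[[length(index_rows) + 1]] <- data.frame(
          stage = stage, group = grp, indicator = ind, index_kind = kind,
          lambda1 = pr$lambda1, lambda2 = pr$lambda2, r = pr$r, n = pr$n,
          stringsAsFactors = FALSE)
      }

      for (fs in config$feature_sets) {
        Xf <- tryCatch(
          build_features(fs, g_refl, g_deriv, g_tri, sel),
          error = function(e) {
            message("skipping feature set ", fs, " for ", ind, "/", grp,
                    ": ", conditionMessage(e))
            NULL
          })
        if (is.null(Xf)) next
        for (mod in config$models) {
          rep_row <- evaluate_model(mod, Xf, y, split, seed = config$seed)
          rep_row <- cbind(data.frame(stage = stage, group = grp,
                                      indicator = ind, feature_set = fs,
                                      stringsAsFactors = FALSE), rep_row)
          model_rows[[length(model_rows) + 1]] <- rep_row
        }
      }
    }
  }

  model_tables <- do.call(rbind, model_rows)
  best_features <- NULL
  if (!is.null(model_tables)) {
    key <- interaction(model_tables$model, model_tables$indicator,
                       model_tables$group, drop = TRUE)
    best_features <- do.call(rbind, lapply(split(model_tables, key),
      function(d) d[which.max(d$r2_test), , drop = FALSE]))
    rownames(best_features) <- NULL
    best_features <- best_features[order(best_features$model,
                                         best_features$indicator,
                                         best_features$group), ]
  }

  # per-group red-edge summaries from the trilateral table
  red_edge <- do.call(rbind, lapply(groups, function(grp) {
    gi <- which(table$physiology$group == grp)
    data.frame(stage = stage, group = grp,
               lambda_r = mean(tri[gi, "lambda_r"]),
               Dr = mean(tri[gi, "Dr"]), SDr = mean(tri[gi, "SDr"]),
               stringsAsFactors = FALSE)
  }))

  # amplitude of variation per indicator, per date and stage mean
  phys <- table$physiology
  present <- intersect(INDICATORS, names(phys))
  eta_rows <- list()
  for (ind in present) {
    for (d in unique(phys$date)) {
      sub <- phys[phys$date == d, ]
      eta_rows[[length(eta_rows) + 1]] <- data.frame(
        stage = stage, indicator = ind, date = d,
        eta = amplitude_of_variation(mean(sub[[ind]][sub$group == "T"]),
                                     mean(sub[[ind]][sub$group == "CK"])),
        stringsAsFactors = FALSE)
    }
    eta_rows[[length(eta_rows) + 1]] <- data.frame(
      stage = stage, indicator = ind, date = "stage_mean",
      eta = amplitude_of_variation(mean(phys[[ind]][phys$group == "T"]),
                                   mean(phys[[ind]][phys$group == "CK"])),
      stringsAsFactors = FALSE)
  }

  report <- structure(
    list(stage = stage,
         band_tables = do.call(rbind, band_rows),
         index_tables = do.call(rbind, index_rows),
         model_tables = model_tables,
         best_features = best_features,
         red_edge = red_edge,
         eta = do.call(rbind, eta_rows)),
    class = "stage_report")
  if (!is.null(out_dir)) write_stage_report(report, out_dir)
  report
}

#' Write every table of a stage report as CSV
#' @param report A `stage_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_stage_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("band_tables", "index_tables", "model_tables",
               "best_features", "red_edge", "eta")) {
    if (!is.null(report[[nm]])) {
      utils::write.csv(report[[nm]],
                       file.path(out_dir,
                                 paste0(report$stage, "_", nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  invisible(out_dir)
}

#' Cross-stage comparison of control and treatment groups
#'
#' Per-stage CK-T red-edge position shift (positive = red shift of the
#' treatment group), cross-stage orderings of red-edge amplitude and
#' area, the stage-mean amplitude of variation per indicator, and the
#' tally of the most frequently best-performing feature set across all
#' model tables.
#'
#' @param reports List of `stage_report`s (>= 2 stages).
#' @return List with `red_edge_shift`, `ordering`, `eta`,
#'   `best_feature_tally`.
#' @export
compare_groups <- function(reports) {
  if (length(reports) < 2) stop("need at least two stage reports")
  shift <- do.call(rbind, lapply(reports, function(rep) {
    re <- rep$red_edge
    d <- re$lambda_r[re$group == "T"] - re$lambda_r[re$group == "CK"]
    data.frame(stage = rep$stage, shift_nm = d,
               direction = ifelse(d > 0, "red shift",
                                  ifelse(d < 0, "blue shift", "none")),
               stringsAsFactors = FALSE)
  }))
  re_all <- do.call(rbind, lapply(reports, function(rep) rep$red_edge))
  ordering <- do.call(rbind, lapply(split(re_all, re_all$group),
    function(d) data.frame(
      group = d$group[1],
      amplitude_order = paste(d$stage[order(-d$Dr)], collapse = " > "),
      area_order = paste(d$stage[order(-d$SDr)], collapse = " > "),
      stringsAsFactors = FALSE)))
  rownames(ordering) <- NULL
  eta <- do.call(rbind, lapply(reports, function(rep) {
    rep$eta[rep$eta$date == "stage_mean", c("stage", "indicator", "eta")]
  }))
  tally <- NULL
  bf <- do.call(rbind, lapply(reports, function(rep) rep$best_features))
  if (!is.null(bf)) {
    tab <- sort(table(bf$feature_set), decreasing = TRUE)
    tally <- data.frame(feature_set = names(tab),
                        times_best = as.integer(tab),
                        stringsAsFactors = FALSE)
  }
  list(red_edge_shift = shift, ordering = ordering, eta = eta,
       best_feature_tally = tally)
}
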
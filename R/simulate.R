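#' Latent plant state behind a simulated canopy spectrum
#'
#' @param chlorophyll_level Chlorophyll status in \[0,1\]; drives the
#'   red-edge inflection (715 + 20*level nm) and the visible baseline.
#' @param stress_level Heat-stress intensity in \[0,1\]; exactly 0 for
#'   control (CK) plants. Raises the NIR plateau and (through the
#'   indicator coupling) depresses most physiological indicators.
#' @param stage Growth stage: `"branching"`, `"budding"` or
#'   `"flowering"`.
#' @param structure_level Canopy structure in \[0,1\]; drives the NIR
#'   plateau height.
#' @return An object of class `latent_state`.
#' @export
latent_state <- function(chlorophyll_level, stress_level = 0,
                         stage = c("branching", "budding", "flowering"),
                         structure_level = 0.5) {
  stage <- match.arg(stage)
  lv <- c(chlorophyll_level, stress_level, structure_level)
  if (any(lv < 0) || any(lv > 1)) {
    stop("all latent levels must lie in [0, 1]")
  }
  structure(list(chlorophyll_level = chlorophyll_level,
                 stress_level = stress_level, stage = stage,
                 structure_level = structure_level),
            class = "latent_state")
}

#' Default coupling from latent state to physiological indicators
#'
#' Each indicator is `intercept + chl_slope*chlorophyll + stress_slope*
#' stress + N(0, noise_sd)`, truncated to its admissible range. The sign
#' structure encodes the heat-stress response of reclamation herbs: stress
#' depresses SPAD, A, gsw, Ci, Fv'/Fm' and qP and raises qN
#' (non-photochemical dissipation of excess excitation). Noise standard
#' deviations are 5% of each indicator's realistic span.
#'
#' @return data.frame with columns `indicator, intercept, chl_slope,
#'   stress_slope, noise_sd, lower, upper`.
#' @export
default_coupling <- function() {
  data.frame(
    indicator    = INDICATORS,
    intercept    = c(25,   6,    0.12, 240,  0.45,  0.40, 0.70),
    chl_slope    = c(25,   10,   0.25, 60,   0.25,  0.35, -0.20),
    stress_slope = c(-8,  -5,   -0.12, -60, -0.10, -0.15, 0.45),
    noise_sd     = c(2.0,  1.0,  0.02, 7.5,  0.015, 0.02, 0.04),
    lower        = c(0,   -Inf,  0,    0,    0,     0,    0),
    upper        = c(Inf,  Inf,  Inf,  Inf,  1,     1,    Inf),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Defines the synthetic study: paired CK/T pots over three growth
#' stages, 1-nm spectra 350-1350 nm, additive and smooth multiplicative
#' spectral noise, and the latent-to-indicator coupling.
#'
#' @param n_per_group Samples per group per stage (>= 2; default 40, the
#'   per-stage group size of the study design this emulates).
#' @param stages Growth stages to simulate.
#' @param seed Integer seed; the whole experiment is reproducible from it.
#' @param grid Wavelength grid (start 350, stop 1350, step 1 nm).
#' @param noise_sd_additive sd of i.i.d. additive reflectance noise.
#' @param noise_sd_smooth sd of the coefficients of the smooth (cubic)
#'   multiplicative perturbation.
#' @param coupling Indicator coupling table (see [default_coupling()]).
#' @param stress_ranges Per-stage uniform ranges for T-group stress,
#'   increasing from branching to budding as stress duration accumulates.
#' @param chl_stress_coef Chlorophyll inhibition by heat: each treated
#'   sample's chlorophyll level is reduced by `chl_stress_coef * stress`
#'   (clamped at 0), shifting the red edge toward the blue as leaf
#'   chlorophyll degrades under stress.
#' @param chl_ranges,structure_ranges Per-stage uniform ranges of the
#'   other latent levels (chlorophyll rises to budding then falls;
#'   structure accumulates monotonically).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 40,
                       stages = c("branching", "budding", "flowering"),
                       seed = 1,
                       grid = 350:1350,
                       noise_sd_additive = 0.002,
                       noise_sd_smooth = 0.01,
                       coupling = default_coupling(),
                       stress_ranges = list(branching = c(0.1, 0.4),
                                            budding = c(0.4, 0.8),
                                            flowering = c(0.5, 0.8)),
                       chl_stress_coef = 0.3,
                       chl_ranges = list(branching = c(0.35, 0.65),
                                         budding = c(0.55, 0.85),
                                         flowering = c(0.45, 0.75)),
                       structure_ranges = list(branching = c(0.2, 0.5),
                                               budding = c(0.4, 0.7),
                                               flowering = c(0.5, 0.8))) {
  if (n_per_group < 2) stop("n_per_group must be at least 2")
  if (noise_sd_additive < 0 || noise_sd_smooth < 0) stop("noise sds must be >= 0")
  if (min(grid) < 350 || max(grid) > 1350) {
    stop("grid must lie within 350-1350 nm")
  }
  step <- unique(diff(grid))
  if (length(step) != 1) stop("grid must be uniform")
  if ((max(grid) - min(grid)) %% step != 0) stop("step must divide the range")
  missing_ind <- setdiff(INDICATORS, coupling$indicator)
  if (length(missing_ind)) {
    stop("coupling must define all indicators; missing: ",
         paste(missing_ind, collapse = ", "))
  }
  structure(list(n_per_group = n_per_group, stages = stages, seed = seed,
                 grid = grid, noise_sd_additive = noise_sd_additive,
                 noise_sd_smooth = noise_sd_smooth, coupling = coupling,
                 stress_ranges = stress_ranges, chl_ranges = chl_ranges,
                 structure_ranges = structure_ranges,
                 chl_stress_coef = chl_stress_coef),
            class = "sim_config")
}

#' Simulate one canopy reflectance spectrum
#'
#' Deterministic shape: `R(l) = V(l)*(1 - L(l)) + P*L(l)` where `L` is a
#' logistic step of scale 10 nm with inflection `715 + 20*chlorophyll` nm
#' (the red edge), `V(l) = v0 + g*exp(-(l-550)^2/(2*30^2))` is the visible
#' region with baseline `v0 = 0.08 - 0.04*chlorophyll` and green-peak
#' amplitude `g = 0.06*(1 - 0.5*chlorophyll)`, and the NIR plateau is
#' `P = 0.30 + 0.15*structure + 0.08*stress`. Noise: a smooth cubic
#' multiplicative perturbation (coefficient sd `noise_sd_smooth`) plus
#' i.i.d. additive noise (`noise_sd_additive`); values clipped to \[0,1\].
#'
#' @param latent A [latent_state].
#' @param grid Ascending grid within 350-1350 nm.
#' @param noise_sd_additive,noise_sd_smooth Noise levels (0 = noiseless).
#' @param seed Optional integer; when given the draw is made reproducible
#'   without disturbing the caller's RNG stream.
#' @param metadata Metadata list attached to the returned spectrum.
#' @return A reflectance [spectrum].
#' @export
simulate_canopy_spectrum <- function(latent, grid = 350:1350,
                                     noise_sd_additive = 0,
                                     noise_sd_smooth = 0,
                                     seed = NULL, metadata = list()) {
  if (any(diff(grid) <= 0)) stop("grid must be ascending")
  if (min(grid) < 350 || max(grid) > 1350) {
    stop("grid must lie within the supported 350-1350 nm range")
  }
  gen <- function() {
    chl <- latent$chlorophyll_level
    lambda_re <- 715 + 20 * chl
    L <- stats::plogis((grid - lambda_re) / 10)
    v0 <- 0.08 - 0.04 * chl
    g <- 0.06 * (1 - 0.5 * chl)
    V <- v0 + g * exp(-(grid - 550)^2 / (2 * 30^2))
    P <- 0.30 + 0.15 * latent$structure_level + 0.08 * latent$stress_level
    R <- V * (1 - L) + P * L
    if (noise_sd_smooth > 0) {
      t <- (grid - 850) / 500
      coef <- stats::rnorm(4, 0, noise_sd_smooth)
      R <- R * (1 + coef[1] + coef[2] * t + coef[3] * t^2 + coef[4] * t^3)
    }
    if (noise_sd_additive > 0) {
      R <- R + stats::rnorm(length(grid), 0, noise_sd_additive)
    }
    pmin(pmax(R, 0), 1)
  }
  vals <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  spectrum(grid, vals, kind = "reflectance", metadata = metadata)
}

#' Map a latent state to the seven physiological indicators
#'
#' @param latent A [latent_state].
#' @param coupling Coupling table (see [default_coupling()]).
#' @param seed Optional integer for a reproducible isolated draw.
#' @return Named numeric vector over [INDICATORS].
#' @export
latent_to_physiology <- function(latent, coupling = default_coupling(),
                                 seed = NULL) {
  missing_ind <- setdiff(INDICATORS, coupling$indicator)
  if (length(missing_ind)) {
    stop("coupling missing indicators: ", paste(missing_ind, collapse = ", "))
  }
  gen <- function() {
    idx <- match(INDICATORS, coupling$indicator)
    mu <- coupling$intercept[idx] +
      coupling$chl_slope[idx] * latent$chlorophyll_level +
      coupling$stress_slope[idx] * latent$stress_level
    v <- mu + stats::rnorm(length(mu), 0, coupling$noise_sd[idx])
    v <- pmin(pmax(v, coupling$lower[idx]), coupling$upper[idx])
    stats::setNames(v, INDICATORS)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# two synthetic measurement dates per stage, for the eta-by-date reports
.stage_dates <- list(branching = c("2023-05-12", "2023-05-22"),
                     budding = c("2023-06-08", "2023-06-18"),
                     flowering = c("2023-07-04", "2023-07-14"))

#' Simulate the full paired CK/T experiment
#'
#' For each configured stage: `n_per_group` control samples (stress 0) and
#' `n_per_group` treatment samples with stress drawn from the
#' stage-dependent range, spectra and physiology aligned by sample id.
#' Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config].
#' @return Named list of [sample_table] objects, one per stage.
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    out <- list()
    for (stage in config$stages) {
      n <- config$n_per_group
      groups <- rep(c("CK", "T"), each = n)
      chl_r <- config$chl_ranges[[stage]]
      str_r <- config$structure_ranges[[stage]]
      sts_r <- config$stress_ranges[[stage]]
      chl <- stats::runif(2 * n, chl_r[1], chl_r[2])
      strc <- stats::runif(2 * n, str_r[1], str_r[2])
      sts <- c(rep(0, n), stats::runif(n, sts_r[1], sts_r[2]))
      # heat degrades leaf chlorophyll -> blue shift of the red edge in T
      chl <- pmax(0, chl - config$chl_stress_coef * sts)
      ids <- sprintf("%s_%s_%02d", stage, groups, c(seq_len(n), seq_len(n)))
      dates <- rep(.stage_dates[[stage]], length.out = 2 * n)
      spectra <- vector("list", 2 * n)
      phys <- matrix(NA_real_, 2 * n, length(INDICATORS),
                     dimnames = list(ids, INDICATORS))
      for (i in seq_len(2 * n)) {
        lat <- latent_state(chl[i], sts[i], stage, strc[i])
        md <- list(sample_id = ids[i], group = groups[i], stage = stage,
                   date = dates[i], pot = ((i - 1) %% 4) + 1, replicate = 1)
        spectra[[i]] <- simulate_canopy_spectrum(
          lat, config$grid,
          noise_sd_additive = config$noise_sd_additive,
          noise_sd_smooth = config$noise_sd_smooth, metadata = md)
        phys[i, ] <- latent_to_physiology(lat, config$coupling)
      }
      mat <- spectra_matrix(spectra)
      physiology <- data.frame(sample_id = ids, group = groups,
                               stage = stage, date = dates,
                               as.data.frame(phys),
                               stringsAsFactors = FALSE, row.names = NULL)
      out[[stage]] <- sample_table(mat, config$grid, physiology,
                                   kind = "reflectance",
                                   metadata = spectra_metadata(spectra))
    }
    out
  })
}
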
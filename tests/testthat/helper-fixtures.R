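# Small fixtures built in code, shared across test files.

# logistic "red edge" reflectance with analytic derivative
logistic_spectrum <- function(grid = 350:1350, inflection = 725, scale = 10,
                              base = 0.05, plateau = 0.5) {
  L <- plogis((grid - inflection) / scale)
  list(
    refl = spectrum(grid, base + (plateau - base) * L, kind = "reflectance"),
    deriv = spectrum(grid,
                     (plateau - base) / scale * L * (1 - L),
                     kind = "first_derivative"),
    inflection = inflection, scale = scale, base = base, plateau = plateau
  )
}

# closed-form logistic reflectance value (for dense-grid oracles)
logistic_refl_fun <- function(inflection = 725, scale = 10, base = 0.05,
                              plateau = 0.5) {
  function(l) base + (plateau - base) * plogis((l - inflection) / scale)
}

random_spectra <- function(n, grid = seq(400, 900, by = 10), seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    spectrum(grid, runif(length(grid), 0.05, 0.6), kind = "reflectance",
             metadata = list(sample_id = sprintf("s%02d", i), group = "CK",
                             stage = "branching", date = "2023-05-12",
                             pot = 1, replicate = i))
  }))
}

# small sample_table with planted linear structure for selection tests
toy_table <- function(n = 24, bands = 21, seed = 7) {
  withr::with_seed(seed, {
    wl <- seq(500, 500 + 5 * (bands - 1), by = 5)
    X <- matrix(runif(n * bands, 0, 1), n, bands,
                dimnames = list(sprintf("s%02d", seq_len(n)),
                                as.character(wl)))
    list(X = X, wl = wl)
  })
}
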
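#!/usr/bin/env Rscript
# Step 2: preprocessing and red-edge behaviour.
#
# Reads the step-1 CSV exports, applies the standard chain (resample to
# the 1-nm grid, Savitzky-Golay window 11 / order 2), computes
# first-derivative spectra and summarises the red edge per group and
# stage: position (lambda_r), amplitude (Dr) and area (SDr).

suppressMessages(library(heatspec))

data_dir <- "scratch/data"
if (!dir.exists(data_dir)) stop("run analysis/01_simulate.R first")
stages <- c("branching", "budding", "flowering")

red_edge <- list()
for (st in stages) {
  spectra <- read_spectra_table(file.path(data_dir,
                                          paste0(st, "_spectra.csv")),
                                dialect = "wide_csv")
  phys <- read_physiology_table(file.path(data_dir,
                                          paste0(st, "_physiology.csv")))
  tb <- validate_alignment(spectra, phys)
  refl <- smooth_table(tb, 11, 2)
  deriv <- derivative_table(refl)
  tri <- trilateral_table(refl, derivative = deriv)
  for (g in c("CK", "T")) {
    gi <- which(tb$physiology$group == g)
    red_edge[[paste(st, g)]] <- data.frame(
      stage = st, group = g,
      lambda_r = mean(tri[gi, "lambda_r"]),
      Dr = mean(tri[gi, "Dr"]),
      SDr = mean(tri[gi, "SDr"]))
  }
}
red_edge <- do.call(rbind, red_edge)
rownames(red_edge) <- NULL
write.csv(red_edge, "results/02_red_edge_summary.csv", row.names = FALSE)

print(red_edge, digits = 4)
shift <- red_edge$lambda_r[red_edge$group == "T"] -
  red_edge$lambda_r[red_edge$group == "CK"]
cat("\nCK-to-T red-edge shift (nm) per stage:",
    paste(sprintf("%+.2f", shift), collapse = ", "), "\n")
cat("Negative values are blue shifts: chlorophyll degradation under heat\n")
cat("moves the derivative maximum toward shorter wavelengths.\n")
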
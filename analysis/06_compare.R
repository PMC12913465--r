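#!/usr/bin/env Rscript
# Step 6: cross-stage CK vs T comparison.
#
# Aggregates the stage reports of step 5: red-edge shifts, amplitude and
# area orderings across stages, the per-indicator amplitude of variation
# (eta, percent of the control mean) and the best-feature tally.

suppressMessages(library(heatspec))

seed <- 1
exps <- simulate_experiment(sim_config(seed = seed))
pcfg <- pipeline_config(indicators = list(branching = "SPAD",
                                          budding = "SPAD",
                                          flowering = "SPAD"),
                        models = "SVR", feature_sets = c("NDVI", "FDNDVI"),
                        stride = 5, seed = seed)
reports <- lapply(exps, run_stage_analysis, config = pcfg)
cmp <- compare_groups(reports)

write.csv(cmp$red_edge_shift, "results/06_red_edge_shift.csv",
          row.names = FALSE)
write.csv(cmp$eta, "results/06_eta_by_stage.csv", row.names = FALSE)

cat("Red-edge shift of T relative to CK:\n")
print(cmp$red_edge_shift, row.names = FALSE)
cat("\nRed-edge amplitude/area ordering across stages:\n")
print(cmp$ordering, row.names = FALSE)
cat("\nStage-mean amplitude of variation (eta, %):\n")
eta_wide <- reshape(cmp$eta, idvar = "indicator", timevar = "stage",
                    direction = "wide")
print(eta_wide, row.names = FALSE, digits = 3)
cat("\neta is negative for SPAD and the photosynthetic indicators and\n")
cat("positive for qN in every stage: heat stress depresses assimilation\n")
cat("and shifts energy dissipation to the non-photochemical pathway.\n")
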
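# heatspec

Hyperspectral detection of subsurface heat stress in reclamation
vegetation. On coal gangue dumps, spontaneous combustion of waste rock
heats the root zone of herbaceous cover (alfalfa in the motivating
system) long before any damage is visible. `heatspec` implements the
full canopy-spectroscopy workflow used to monitor that stress: from raw
reflectance spectra (350–1350 nm) and paired physiological measurements
to stress-sensitive spectral features and regression models that predict
the physiology from the spectra alone.

It is aimed at plant-stress and vegetation remote-sensing researchers
who have (or want to prototype against) paired canopy spectra and
physiological indicators — SPAD chlorophyll, gas exchange (A, gsw, Ci)
and chlorophyll fluorescence (Fv'/Fm', qP, qN) — for a control (CK)
versus treatment (T) design across growth stages.

## What it computes

* **Preprocessing** — de-duplication, resampling to the canonical 1-nm
  grid, Savitzky–Golay smoothing (window 11, order 2 by default) and
  first-derivative reflectance FDR(λ) by central differences.
* **Trilateral (three-edge) parameters** — the 20 positional, amplitude,
  area and ratio descriptors of the blue edge, yellow edge, red edge
  (680–780 nm), green peak and red valley: Dr, λr, Db, λb, Dy, λy, Rg,
  λg, Rr, λv, SDr, SDb, SDy, (Rg−Rr)/(Rg+Rr), Rg/Rr, SDr/SDb, SDr/SDy,
  SDr−SDb, (SDr−SDb)/(SDr+SDb), (SDr−SDy)/(SDr+SDy).
* **Per-band correlation screening** — Pearson r(λ) between each band
  and an indicator; top-10 band sets (OS1/FDS1).
* **SPA band selection** — the Successive Projections Algorithm: forward
  selection maximising the residual norm after orthogonal projection on
  the already-selected bands, with start band and subset size chosen by
  K-fold cross-validated RMSE of a multiple linear regression (RMSECV);
  yields OS2/FDS2.
* **Two-band index optimisation** — exhaustive search over all ordered
  band pairs for RVI = R(λ1)/R(λ2), NDVI = (R(λ1)−R(λ2))/(R(λ1)+R(λ2)),
  DVI = R(λ1)−R(λ2) and their first-derivative counterparts FDRVI,
  FDNDVI, FDDVI, maximising |r| with the indicator.
* **Regression models** — ε-SVR (RBF kernel, ε = 0.01, tuned C/γ),
  random forest (200 trees, minimum node size 5) and PLSR
  (CV-chosen components), fitted on a seeded 3:1 train:test split and
  scored with R² = 1 − Σ(y−ŷ)²/Σ(y−ȳ)² and RMSE = √(Σ(y−ŷ)²/N).
* **Group comparison** — the amplitude of variation
  η = (v_T − v_CK)/v_CK × 100 %, red-edge shifts and cross-stage
  orderings.
* **A synthetic experiment generator** — paired CK/T canopy spectra with
  a green peak, red valley, sigmoid red edge (inflection 715–735 nm) and
  NIR plateau (0.30–0.55), coupled to the seven indicators with the sign
  structure heat stress imposes (T lower on SPAD, A, gsw, Ci, Fv'/Fm',
  qP; higher on qN), so the whole pipeline is testable without field
  data.

## Worked example

```r
library(heatspec)

# a three-stage CK/T experiment: 40 + 40 samples per stage
exps <- simulate_experiment(sim_config(seed = 1))
tb   <- exps$budding

# preprocess and extract the red edge of the first sample
sm     <- smooth_table(tb)                     # SG window 11, order 2
deriv1 <- first_derivative(spectrum(sm$wavelengths, sm$spectra[1, ]))
round(red_edge_summary(deriv1), 4)
#> lambda_r       Dr      SDr
#> 730.0000   0.0083   0.3042

# optimal derivative index for SPAD, fitted on the training partition
y  <- tb$physiology$SPAD
sp <- split_train_test(80, seed = 1)          # 60 train / 20 test
d  <- derivative_table(sm)
pr <- optimize_band_pair(d$spectra[sp$train, ], tb$wavelengths,
                         y[sp$train], "FDNDVI")
pr
#> <FDNDVI(709, 746): r = -0.870, n = 60>

# SVR on that single index feature
X <- matrix(apply_band_pair(d$spectra, tb$wavelengths, pr), ncol = 1)
round(evaluate_model("SVR", X, y, sp, seed = 1)[, c("r2_test", "rmse_test")], 3)
#>   r2_test rmse_test
#> 1   0.674     3.147
```

The FDNDVI pair straddles the red edge (709/746 nm): its value tracks
the red-edge position, which moves with chlorophyll, which is what SPAD
measures — a single optimised band ratio predicts held-out SPAD with
R² ≈ 0.7 and an RMSE of ≈ 3 SPAD units.

The `analysis/` directory holds the numbered workflow
(`01_simulate.R` … `06_compare.R`) that runs the study end to end and
writes its tables under `results/`: design summary, red-edge shifts
(blue shifts of −1.3 to −5.0 nm under stress), trilateral correlations,
sensitive bands, the model × feature-set factorial and the η
trajectories (e.g. η(SPAD) = −11 %, −21 %, −27 % across the three
stages; η(qN) = +25 %, +49 %, +58 %).

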
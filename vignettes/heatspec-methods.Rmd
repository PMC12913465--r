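---
title: "Methods: canopy hyperspectra under heat stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canopy hyperspectra under heat stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatspec)
```

## The problem

Vegetation re-established on coal gangue dumps can sit above slowly
combusting waste rock. The resulting root-zone heat stress depresses
photosynthesis long before visible damage, and it leaves fingerprints in
the canopy reflectance spectrum: a higher near-infrared (NIR) plateau, a
deeper visible absorption contrast and a displaced red edge. `heatspec`
turns those fingerprints into quantitative predictors of plant
physiology — relative chlorophyll (SPAD), gas exchange (A, gsw, Ci) and
chlorophyll fluorescence (Fv'/Fm', qP, qN) — for a paired control (CK)
versus treatment (T) design observed at several growth stages.

The workflow has five computational stages, each exposed as plain
functions: preprocessing, trilateral feature extraction, per-band
correlation and SPA band selection, exhaustive two-band index
optimisation, and regression modelling. A synthetic experiment generator
provides data with the statistical structure the analysis assumes, so
every stage is testable end to end.

## The synthetic generator

No public canopy dataset accompanies the motivating field design, so the
generator is a first-class, documented model rather than a test fixture.
Each sample is driven by a latent state: `chlorophyll_level`,
`stress_level` (exactly 0 for CK), `structure_level`, all in [0, 1], and
a growth stage.

**Reflectance.** On the grid $\lambda$ (350–1350 nm, 1 nm):

$$R(\lambda) = V(\lambda)\,(1 - L(\lambda)) + P\,L(\lambda)$$

* $L$ is a logistic step of scale 10 nm with inflection at
  $\lambda_{re} = 715 + 20\,c$ nm for chlorophyll level $c$ — the red
  edge, spanning the conventional 715–735 nm range.
* $V(\lambda) = v_0 + g \exp(-(\lambda-550)^2 / (2\cdot 30^2))$ is the
  visible region: baseline $v_0 = 0.08 - 0.04c$ (chlorophyll absorption
  darkens the red/blue troughs) plus a green peak at 550 nm of amplitude
  $g = 0.06(1 - 0.5c)$.
* $P = 0.30 + 0.15\,s_{struct} + 0.08\,s_{stress}$ is the NIR plateau
  (0.30–0.55 over the admissible latents). Stress raises it — the
  dominant observable group contrast.

Noise has two parts, both with defaults deliberately modest: a smooth
multiplicative perturbation (cubic polynomial in a scaled wavelength,
coefficient sd 0.01) standing in for illumination/calibration drift, and
i.i.d. additive noise (sd 0.002 reflectance units) for sensor noise.
Values are clipped to [0, 1].

**Chlorophyll inhibition.** Heat stress acts on the spectrum through two
channels: the NIR plateau term above, and a chlorophyll channel
`chl <- chl - 0.3 * stress` applied when the experiment is simulated.
The second channel is the scientifically load-bearing one — SPAD *is* a
chlorophyll measurement, and heat degrades chlorophyll — and it produces
the blue shift of the treated group's red edge that the derivative
analysis detects (−1 to −5 nm at the default stress levels, growing with
stress duration). Without it, stress would be visible only as an
amplitude change that normalised (ratio) indices cancel by construction,
and no single normalised index could predict SPAD.

**Physiology.** Each indicator is an affine function of the latent state
plus Gaussian noise, truncated to its admissible range:

| indicator | intercept | chl slope | stress slope | noise sd | range |
|-----------|-----------|-----------|--------------|----------|-------|
| SPAD      | 25        | 25        | −8           | 2.0      | ≥ 0 |
| A         | 6         | 10        | −5           | 1.0      | — |
| gsw       | 0.12      | 0.25      | −0.12        | 0.02     | ≥ 0 |
| Ci        | 240       | 60        | −60          | 7.5      | ≥ 0 |
| Fv'/Fm'   | 0.45      | 0.25      | −0.10        | 0.015    | [0, 1] |
| qP        | 0.40      | 0.35      | −0.15        | 0.02     | [0, 1] |
| qN        | 0.70      | −0.20     | +0.45        | 0.04     | ≥ 0 |

Slopes carry the qualitative stress response of reclamation herbs
(stress depresses everything except non-photochemical quenching qN,
which rises as excess excitation is dissipated as heat); intercepts and
slopes were chosen once to land in realistic alfalfa ranges (SPAD
30–50, A 6–15 µmol m⁻² s⁻¹, gsw 0.2–0.35 mol m⁻² s⁻¹, Ci
240–300 µmol mol⁻¹, Fv'/Fm' 0.5–0.7, qN 0.5–1.0). Noise sds are 5 % of
each indicator's realistic span. Per-stage latent ranges: stress grows
from branching U(0.1, 0.4) through budding U(0.4, 0.8) to flowering
U(0.5, 0.8) (stress duration accumulates); chlorophyll rises to budding
then falls (U(0.35, 0.65) → U(0.55, 0.85) → U(0.45, 0.75)); canopy
structure accumulates monotonically. All of this is `sim_config()`
arguments.

**What the generator does not emulate.** No radiative transfer (no
leaf/canopy optical physics, soil background, illumination geometry or
water bands), no temporal autocorrelation between measurement dates, no
pot or replicate random effects, and the latent-to-indicator map is
linear. Tests passing on this generator therefore demonstrate that the
*algorithms* behave as specified on data with the assumed structure —
not that field data meet those assumptions.

## Preprocessing

* **Resampling**: duplicated wavelengths are collapsed to their mean,
  then linear interpolation onto the canonical integer grid
  350…1350 nm (1001 bands). No extrapolation, ever.
* **Smoothing**: Savitzky–Golay, default window 11 bands / order 2 — a
  standard compromise for 1-nm vegetation spectra. Ends are handled by
  the asymmetric rows of the SG projection matrix (a polynomial fitted
  on the edge window, evaluated off-centre), so polynomials of degree
  ≤ order are reproduced exactly everywhere.
* **Derivative**: central differences on the uniform grid, one-sided at
  the two ends, is the canonical first-derivative reflectance (FDR); an
  SG-derivative is available behind a flag. Both locate a logistic
  inflection to within 1 nm; the downstream analysis is deliberately
  robust to this convention choice.

## Trilateral parameters

Twenty descriptors of the blue edge (490–530 nm), yellow edge
(560–640 nm), red edge (680–780 nm), green peak (510–560 nm) and red
valley (640–700 nm). Only the red-edge window is a field-wide constant;
the other windows are the prevailing literature conventions and
overridable. Conventions this package fixes (and flags, because the
field does not):

* `SDr`/`SDb` integrate the *signed* FDR (trapezoid rule); `SDy`
  integrates `|FDR|` so all three areas are positive and the printed
  ratios `SDr/SDy` etc. stay well-defined.
* `Dy` keeps its sign (the yellow-edge derivative is typically
  negative): correlations against it are meaningfully signed.
* Argmax/argmin ties break toward the shorter wavelength, making
  extraction deterministic.
* Ratio and normalised-difference parameters are `NA` when their
  denominator is exactly 0 (flat spectra).

## Band and index selection

**Correlation screening** is plain per-band Pearson correlation; bands
with zero variance get r = 0 with a flag. The top-10 sets (`OS1`,
`FDS1`) sort by |r|, ties toward shorter wavelengths.

**SPA** follows the classic successive-projections loop: starting from
band $k_0$, every unselected column is replaced by its residual after
orthogonal projection on the most recently selected (already
residualised) column, and the next pick maximises the residual norm.
Because candidates stay residualised, the loop performs successive
orthogonalisation; the implementation is verified index-for-index
against an independent Gram–Schmidt oracle. Columns are mean-centred and
unit-scaled first (standard chemometrics practice, switchable). The
subset size and start band minimise the K-fold (default 5) cross-
validated RMSE of an OLS model on the selection; the sweep exploits the
nesting of SPA's forward path (one run to $N_{max}$ yields all prefixes)
and breaks ties toward smaller subsets, then smaller start bands. Fold
assignment is seeded; inside a fold a rank-deficient OLS falls back to a
ridge solve with regulariser 1e-8. The start-band sweep is quadratic in
bands, so the pipeline sweeps a strided start set (default every 10th
band of the 1-nm grid) — the projection loop itself still works on all
selected candidates.

**Two-band indices** use the universal forms RVI = v₁/v₂,
NDVI = (v₁−v₂)/(v₁+v₂), DVI = v₁−v₂, with FD-prefixed variants applying
the same formulas to derivative values. The optimiser searches *ordered*
pairs on the full grid (the published optimal combinations include pairs
with λ₁ < λ₂ and λ₁ > λ₂), maximising |r| because strong negative
optima are as useful as positive ones; the achieved r is reported with
its sign. Ties break toward smaller λ₁ then λ₂. Samples whose index is
undefined (zero denominator) exclude the pair, with a skip count. The
search is vectorised per λ₁ (index matrix against all λ₂ at once); on
the 1001-band grid one full search over 10⁶ ordered pairs takes a few
seconds, and a `stride` argument coarsens the grid for factorial runs.

## Regression models

Three models, matching common chemometrics practice:

* **SVR**: ε-SVR, RBF kernel, ε = 0.01; penalty C ∈ {0.1, 1, 10, 100}
  and kernel width γ on a five-point log grid 10⁻³…10, chosen by a
  seeded internal 5-fold grid search. Features standardised with
  training statistics.
* **RFR**: 200 trees, minimum node size 5, seeded bootstrap.
* **PLSR**: components chosen by seeded internal 5-fold CV minimising
  RMSECV, capped at min(10, features, n−1, effective rank). Adjacent
  1-nm bands are nearly collinear, so the effective-rank cap (singular
  values > 1e-8 of the largest) keeps component extraction stable; if
  extraction still degenerates in a fold the component count backs off.
  With a single feature, PLS1 with one component coincides exactly with
  simple least squares and is fitted as such.

Scores are R² = 1 − Σ(y−ŷ)²/Σ(y−ȳ)² and RMSE on the raw (unstandardised)
target. Test-set R² uses the test-set mean in the denominator; the
train-mean convention is available via the `ybar` argument. A constant
training target short-circuits every model to a constant predictor.

**Leakage policy.** The 3:1 train:test split (floor for the test size:
80 samples → 60/20) is drawn once per group with the configured seed.
All selectors — top-10 bands, SPA subsets, the TP threshold filter
(|r| > 0.6 on the trilateral parameters) and the optimal index pairs —
are fitted on the training partition only; `selector_scope = "all"`
fits them on all samples of a group for comparability with published
tables built without a held-out partition. A regression test verifies that permuting test labels cannot
change any fitted selector.

## Pipeline and reporting

`run_stage_analysis()` executes preprocessing → trilateral extraction →
band selection → index optimisation → the model × indicator × group ×
feature-set factorial for one stage, and writes every table as CSV.
Default indicators per stage pair SPAD with the stage's most
stress-responsive gas-exchange and fluorescence parameters (branching
and flowering: gsw and qP; budding: A and qN). `compare_groups()`
aggregates stages: red-edge shifts of T against CK (positive = red
shift), amplitude/area orderings, the per-indicator amplitude of
variation η = (v_T − v_CK)/v_CK × 100 %, and the best-feature tally.
η by measurement date uses the two synthetic dates each stage carries;
each stage × group slice is treated as one dataset.

All randomness flows from explicit seeds (`sim_config(seed=)`,
`pipeline_config(seed=)`), and repeated runs emit byte-identical CSVs —
this is tested.

## Problem sizes and numerical choices

The default experiment is 40 CK + 40 T samples per stage on the 1001-
band grid — the group size at which all seven indicator sign contrasts
hold in ≥ 19/20 seeds, and the size used by the acceptance script. The
test suite exercises the optimisers against brute-force oracles at
reduced sizes chosen for coverage per unit time: band-pair search on up
to 50 bands (50 random problems), SPA on up to 12×20 matrices (200
random problems) with subset sizes kept below the centred-matrix rank
(beyond it every residual is numerically zero and any pick is
equivalent), and the factorial pipeline at band strides 5–50. The
analysis scripts run the full factorial at stride 5 and the headline
budding-stage quantities at full resolution.

Degenerate inputs are first-class: constant targets (constant
predictor), zero-variance bands (flagged, r = 0), zero denominators in
ratio indices (NA + skip counting), rank-deficient CV folds (ridge
fallback), and empty TP sets (an error advising a lower threshold, which
the pipeline logs and skips).

## Known limitations

* Within-group (CK-only or T-only) prediction removes most of the
  stress-driven variance; those cells measure the residual chlorophyll
  signal and score substantially lower than pooled CK+T models — visible
  in the step-5 tables.
* The exhaustive pair search over 10⁶ pairs on 60 training samples
  overfits the training correlation by construction; the reported
  test-set scores, not the training |r|, are the meaningful numbers.
* SPA's forward path is unsupervised; the RMSECV criterion chooses among
  reachable paths but cannot force arbitrary band pairs into the
  selection.
* The generator's linear latent-to-indicator map makes nonlinear model
  advantages (SVR vs PLSR) smaller than on field data; model rankings
  here should not be read as general.
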
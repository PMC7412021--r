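---
title: "Methods: growing stock volume retrieval from polarimetric SAR time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growing stock volume retrieval from polarimetric SAR time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polsarvol)
```

## The retrieval problem

Growing stock volume (GSV, m³/ha) is the stem volume of living trees per
hectare, the standard stocking measure of managed forest. Ground truth
comes from square inventory plots: every stem with DBH ≥ 5 cm is measured
for diameter and height, each stem's volume is
`g·(H + 3)·f` with `g = π(dbh/200)²` the breast-height cross-section (m²)
and `f` a dimensionless trunk taper coefficient, and the plot sum is scaled
by the plot area to m³/ha (`plot_gsv()`). Species taper tables are rarely
published; `TaperModel` is therefore pluggable — a constant `f = 0.45` is
the synthetic default and is appropriate only for simulated even-aged
plantation.

The remote predictor is quad-polarimetric L-band SAR. The pixel coherency
matrix T₃ is split by the Yamaguchi four-component decomposition
(`yamaguchi4()`) into surface, double-bounce, volume and helix powers that
sum to the span. Over conifer plantation the trunk–ground double bounce
grows with stocking and the direct ground return shrinks, so besides the
base powers we use four fused characteristics — Dbl/Odd, Vol/Odd, Dbl×Vol,
Dbl×Vol/Odd — that combine mechanisms and, empirically, correlate with GSV
at least as strongly as any single power.

## Retrieval models

Two single-predictor models are fitted per characteristic σ:

* **Exponential GLM.** σ = e^(a₀ + a₁·GSV). The natural-log link turns this
  into ordinary least squares of ln σ on GSV (`fit_gsv_glm()`): no starting
  values, exact recovery on noise-free data, and an unbounded monotone
  inversion GSV = (ln σ − a₀)/a₁ (`invert_gsv()`). Non-positive σ cannot
  enter the log; such observations are excluded and counted rather than
  floored, because adding a floor constant would change the model being
  fitted.

* **Semi-exponential saturation model.**
  σ = β_s + (β_n − β_s)·e^(−GSV/k). β_n is the zero-GSV (bare ground)
  characteristic, β_s the dense-forest asymptote, and k (m³/ha) the
  saturation constant. This is the classic water-cloud-type form: it
  satisfies σ(0) = β_n and σ(∞) = β_s exactly, which is what the two
  parameters mean physically. Inversion
  GSV = −k·ln((σ − β_s)/(β_n − β_s)) exists only while σ lies strictly
  between the asymptote and the zero-GSV value; σ at or beyond β_s returns
  a configurable `gsv_cap` (default 500 m³/ha, just above the densest
  stands the generator produces) with a `saturated` flag, and σ beyond β_n
  returns 0 with a `floored` flag.

The scientific contrast between the two is the invertible range: the GLM
has no ceiling, while the semi-exponential model cannot distinguish stands
beyond its saturation level. Both facts are asserted in the test suite
rather than merely described.

### Nonlinear fitting choices

`fit_gsv_semiexp()` uses Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with a convergence tolerance of 1e-10 on the sum of
squares and at most 500 iterations per attempt. Starting values are taken
from the range of the data: β_n from the mean σ of the 10% of plots with
the lowest GSV, β_s from the 10% highest, and k from the median GSV. On
failure, up to 5 jittered restarts (drawn from a private seed stream, so
user RNG state is untouched) are attempted; a fit that still fails, or
whose k lands on its box bound (1e-6 to 50·max(GSV)), is returned flagged
rather than raising, because in leave-one-out loops a single bad fold must
not abort the protocol. On noise-free model data the fit recovers the
generating parameters to a relative 1e-6.

## The decomposition

`yamaguchi4()` follows the model-based branch logic of the original
four-component method: helix power 2·|Im T₂₃|; volume power from the
cross-polarised channel with the symmetric random-dipole cloud
(diag(2,1,1)/4) when the co-polarised ratio is within ±2 dB and the
oriented-cloud matrices (1/30·[[15,±5,0],[±5,7,0],[0,0,8]]) outside; the
surface/double split of the span residual by the sign of the dominance
criterion. Two numerical decisions matter:

* **Negative intermediates.** Volume power can come out negative on
  surface-dominated pixels, and the surface/double split can overshoot.
  Negative values are clipped to zero and the *span residual*
  (trace − P_vol − P_hlx) is what gets split, so the four powers always sum
  to trace(T₃) exactly — the power-sum identity is checked to 1e-8 on
  thousands of random PSD matrices. "Rotated" and other improved variants
  of the decomposition are deliberately out of scope.
* **Ratio features at Odd = 0.** Fusing divides by the surface power;
  pixels or plots with zero Odd get `NA` ratio features, propagated
  downstream, never silently replaced by zero.

Plot values are extracted from rasters by a 7×7 window mean centred on the
pixel containing the plot centre (`extract_plot_value()`): the window
matches a ~30 m plot to ~4 m pixels after multilooking. Windows must be
odd; a plot whose window is more than half masked is unusable (the 50%
threshold is a package decision, configurable), and shadow-flagged plots
are discarded before any fitting.

## Temporal fusion

Powers from acquisitions a few weeks apart differ — soil moisture and wind
perturb the scattering even though GSV is static within a season. The
package therefore averages the *base powers* arithmetically across an
acquisition combination per plot and recomputes the fused characteristics
from the averaged powers (`temporal_average()`). Average-then-fuse was an
open design point: averaging per-acquisition ratios instead gives a
different estimator (for powers (odd, dbl) of (1,4) and (4,1) the two
orders give Dbl/Odd of 1 vs 2.125). Averaging powers first is the physical
choice — the mean power is the quantity speckle averaging estimates — and
the other order remains available via `fuse_first = TRUE` for sensitivity
analysis.

## Assessment protocol

Characteristics are screened by the Pearson coefficient with a two-tailed
t test (`pearson_table()`); the critical value is always computed from the
actual post-exclusion n via `critical_r(n, alpha)` rather than hard-coded,
because the usable plot count varies with shadow masking. Retrieval skill
is measured by leave-one-out cross-validation (`loocv_gsv()`): each plot
is predicted from a model refitted — including the semi-exponential
initialisation rule — on the other n−1 plots. Metrics (`gsv_metrics()`)
are RMSE, RRMSE = 100·RMSE/mean(observed), and R². R² here is the squared
Pearson correlation of observed and LOOCV-predicted GSV; the alternative
1 − SSE/SST can be negative for cross-validated predictions, which
published accuracy tables never show, so it is relegated to
`r2_method = "ess"`. The exceedance fraction counts plots with relative
error above a threshold that defaults to 0.5 (50%) — reports always state
the threshold used, since no canonical value exists.

`aggregate_correlations()` averages single-image correlations per feature,
optionally dropping non-significant entries, and rounds half-away-from-zero
to 3 decimals, the convention of published correlation tables (banker's
rounding would turn −0.5095 into −0.510 vs −0.509 depending on parity).
`reference_correlations()` ships a published four-acquisition correlation
table for an L-band Chinese fir plantation study as the reference input for
this aggregation and as the calibration yardstick for the generator.

## What the synthetic generator emulates — and what it does not

`scene_config()` fixes the study conditions:

* **Plots.** 50 plots, GSV drawn from a three-stratum uniform mixture —
  young (60–150 m³/ha, weight 10%), immature (150–300, 52%), mature
  (300–450, 38%) — matching the age-class composition of a managed fir
  plantation. Tree lists are built so that the stem-volume formula applied
  to the list reproduces the drawn GSV within 1% (the last tree is sized to
  close the volume gap exactly), with DBH ≥ 5 cm and heights on a monotone
  DBH–height curve. A single constant-GSV stratum is allowed (useful for
  variance checks); an accidentally zero-width multi-stratum law is refused
  because downstream correlations would be undefined.
* **Powers.** ln σ = a₀ + a₁·GSV + bias_t + ε per base characteristic, the
  same exponential law the GLM inverts. Default slopes (per m³/ha):
  Odd −0.0030, Dbl +0.0035, Vol +0.0015, Hlx 0 — the observed sign pattern
  at L band. Shared log-noise SD 0.45 plus per-acquisition disturbance
  (0, 0.20, 0.25, 0.10 for the four default acquisitions, with small
  per-characteristic biases emulating two post-rain and one windy image).
  These magnitudes were chosen once so that single-image |Pearson|
  correlations land in the 0.4–0.7 band typical of published single-scene
  results; no quantitative noise model exists to calibrate against.
* **Speckle.** Optional complex-Wishart multilook draws (`sim_t3()`),
  disabled by default for plot-level tables: after 7×7 spatial averaging,
  plot-level noise is approximately log-normal, which the ε term already
  models.
* **Seeding.** All randomness derives from one root seed through fixed
  per-operation offsets (plots, trees, powers, speckle, restarts), so every
  table is bit-reproducible and operations can be regenerated independently.

The generator does **not** simulate electromagnetic canopy scattering,
terrain or DEM effects, real weather covariates, geocoding error, or
spatial autocorrelation between plots. Passing tests therefore demonstrate
the correctness and internal consistency of the estimation machinery and
the direction of the temporal-fusion and saturation effects — not the
absolute accuracy obtainable from real imagery of a particular forest.

## Replicated experiments and problem sizes

`temporal_gain_study()` reruns the core comparison — LOOCV RRMSE of a
predictor from each single acquisition vs the four-acquisition temporal
average, both models — over seeded replicate scenes. The packaged studies
use 100 replicates of 50 plots with the Dbl×Vol/Odd predictor, enough to
make the median contrasts stable while keeping a full run in the order of
minutes on one core. The saturation contrast is measured on the same
replicates: the GLM inversion at a σ corresponding to very large GSV
returns that GSV (no ceiling), while the semi-exponential inversion at or
beyond its fitted asymptote returns the cap.

## The pipeline

`run_gsv_pipeline()` chains simulate → shadow exclusion → per-source
features (four singles and five temporal combinations by default) →
Pearson screening → per-cell fit + LOOCV + metrics, writing feature
tables, the correlation table, the evaluation report (CSV), fits (JSON)
and a manifest with the config hash and seed. Default predictors are Dbl
and the four fused characteristics; Odd is screened but not used for
retrieval (it reflects the unvegetated ground), and Vol's correlation is
too weak and inconsistent to stand alone. `map_gsv()` inverts a fitted
model per pixel over co-registered power rasters, with masked pixels set
to `NA` and optional clamping of GLM output to [0, gsv_cap] for mapping.
Rasters are lightweight in-memory matrices with pixel-centre
georeferencing (`power_raster()`), persisted as plain CSV with a two-line
header; this container deliberately stays format-agnostic — co-registration
and geocoding are upstream concerns.

## Known limitations

* Single-predictor models only; no multivariate combination of
  characteristics.
* The decomposition implements the original four-component branch logic;
  orientation-compensated variants would reduce negative-power clipping on
  sloped terrain but are out of scope.
* The semi-exponential fit is a local optimiser with heuristic starts;
  pathological data can converge to a flagged boundary solution, which
  downstream code must check (`converged`, `k_at_bound`).
* Between-model significance testing of accuracy differences is not
  implemented; the report supports paired comparisons externally.
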
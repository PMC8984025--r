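---
title: "Intra-field rice yield prediction: models, simulator, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intra-field rice yield prediction: models, simulator, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(paddy)
```

## The problem

Grain yield in a flooded rice field varies substantially within the field:
soil texture, nutrient status and water availability differ from place to
place, and this heterogeneity is visible from the air long before harvest.
A UAV carrying a multispectral sensor (blue, green, red, red-edge,
near-infrared) and a thermal camera can map that variation weekly at
centimeter resolution. The question this package addresses is how well
such imagery, summarized as six vegetation indices plus canopy
temperature on a 50 cm grid, predicts the yield map the combine harvester
will eventually record — and which modelling strategy extracts the most
from it.

Five models compete on identical inputs:

* a **null model** (training-mean yield everywhere) — the floor any useful
  model must beat;
* **ordinary least squares** on the seven per-pixel features;
* **gradient boosted trees** (squared-error objective, learning rate 0.2,
  depth 2, 200 rounds) — per-pixel, but nonlinear with pairwise
  interactions;
* a **2D convolutional autoencoder** mapping a 5×5-pixel, 7-feature patch
  from a single flyover to the 5×5 yield patch at the same location;
* a **3D convolutional autoencoder** whose encoder also convolves across
  five flyover dates spanning the reproductive phase.

The autoencoder-like shape (conv encoder → dense bottleneck → conv
decoder) is the interesting part: rather than reconstructing its input it
regresses a *label image*, and because each output pixel draws on the
whole input patch, per-pixel sensor noise is averaged away — a spatial
denoising effect that per-pixel models cannot express.

## Evaluation

Four metrics are computed per test region: RMSE, MAE, MBE (mean of
predicted − observed; positive = overprediction) and R², implemented as
the squared product-moment correlation between observed and predicted —
exactly the printed formula, not 1 − SSE/SST. For a constant prediction
(the null model) the correlation is undefined; the package reports an
explicit not-defined marker rather than 0 or silent NaN, and cross-fold
averages drop undefined entries. Relative RMSE (rRMSE) divides by mean
observed yield.

Spatial cross-validation matters here: yield is spatially autocorrelated,
so randomly scattered test pixels would leak information from adjacent
training pixels and inflate every model's apparent skill. The tile grid
is therefore cut into a 4×4 lattice of contiguous blocks, and each of the
four folds assigns whole blocks to roles along broken diagonals — test
blocks on diagonal *k*, validation on diagonal *k*+1, the remaining eight
blocks training (≈50/25/25). Every block is a test block in exactly one
fold, and whole field regions are never seen during training. The
diagonal template is this package's concrete choice for a layout that is
usually drawn only pictorially; it is parameter-free and deterministic.

## The synthetic field generator

The original study's rasters are not publicly deposited, so the package
ships a simulator that reproduces the *statistical structure* the
analysis depends on, making every downstream stage testable end to end.

* **Latent vigor.** A stationary Gaussian random field with
  squared-exponential covariance, zero mean and unit variance, sampled
  exactly by circulant-embedding FFT (oracle-checked against direct
  Cholesky sampling on small grids). The correlation length — the lag at
  which autocorrelation falls to e⁻¹ — defaults to 10 m. No published
  value exists for this quantity; 10 m keeps the yield surface smooth
  within a 2.5 m tile while leaving hundreds of effectively independent
  patches per field, which is the regime the analysis assumes.
* **Yield** is `mean + sd × vigor` (defaults 9.06 ± 0.9 Mg/ha), clipped
  at zero, plus a curvilinear additive artifact emulating
  combine-harvester label noise: sinusoidally offset stripes, default
  amplitude 0.25 Mg/ha, spaced 17 cells ≈ one 8.5 m header width. A 20-cell
  (10 m) edge buffer is masked invalid.
* **Reflectance.** Each band is a logistic-squashed affine function of
  vigor whose gain follows the crop stage: zero before emergence, maximal
  at booting, attenuated during grain fill. NIR rises with vigor; the
  visible bands and red-edge fall as the canopy closes; thermal falls
  (evaporative cooling of a transpiring canopy). A fine-grained (1 m)
  soil-texture field, attenuated as the canopy closes, keeps bare-soil
  scenes from being featureless. I.i.d. sensor noise is added per band
  and values are clamped to [0.005, 1] — a sensor noise floor rather than
  a hard zero, so ratio indices (CIgreen, NAVI) stay defined everywhere.

**Sensor noise defaults to 0.05 reflectance units.** This is deliberately
the dominant per-pixel error source: it stands in for the whole
radiometric error budget of real UAV products (calibration residuals,
BRDF and illumination drift, band-to-band co-registration error, mixed
pixels at 50 cm), not just shot noise. With near-zero noise, per-pixel
regression on simulated indices would be implausibly close to perfect —
real fields show only modest pixel-level index–yield correlation — and
the spatial-denoising phenomenon that distinguishes the convolutional
models would have nothing to denoise.

What the simulator does **not** emulate: geometric/orthomosaic
distortion, radiometric calibration drift between dates, weeds and
soil-pixel misclassification, lodging, and any yield variation *invisible*
to the canopy (the latent field drives both yield and reflectance, so the
asymptotically achievable R² is 1). Passing tests therefore demonstrate
correctness of the machinery and reproduction of the qualitative
phenomena — model ranking, denoising, feature importance — not the
absolute error levels attainable on real fields.

## Network architecture and training

Both networks share the encoder–bottleneck–decoder layout (all layers
ReLU except the final linear 1×1 convolution):

| stage | 2D | 3D |
|---|---|---|
| conv 1 | 64 filters, 3×3, same | 64 filters, 3×3×3, same |
| conv 2 | 128 filters, 2×2, same | 128 filters, 2×2×3, same |
| conv 3 | 256 filters, 1×1, valid | 256 filters, 1×1×5, valid (collapses the 5-date axis) |
| flatten → dense | 6 400 → 256 → 6 400 | identical |
| reshape | (5, 5, 256) | identical |
| decoder | conv 128 2×2 / 64 3×3 / 1 1×1 | identical |

A dense width of 5 400 is sometimes quoted for this design, but the
following reshape to (5, 5, 256) requires exactly 6 400 units; the
package uses 6 400 and `build_cnn2d()` documents the discrepancy.
Parameter counts (3 558 529 and 3 763 201) are asserted in the tests
against hand computations.

Training choices the published protocol leaves open, and what this
package does:

* **Feature standardization**: per-feature mean/sd fitted on the training
  fold only, applied everywhere. Thermal (≈30 °C) and indices (≈0–5)
  differ by orders of magnitude; gradient training needs comparable
  scales.
* **Output bias initialisation**: the final bias starts at the
  training-mean yield, so the untrained network *is* the null model and
  the 50-epoch budget is spent learning deviations, not the offset.
* **Initialisation**: seeded Glorot (fan-based) uniform; all stochastic
  behaviour — weights and epoch shuffling — derives from one integer
  seed, so training is bit-reproducible.
* **Optimizer**: Adam at its conventional defaults (step 1e-3, β₁ 0.9,
  β₂ 0.999, ε 1e-7); the protocol names the optimizer only.
* **Batch size 32** (configurable): conventional at this input size.
* **Checkpointing**: validation MSE after every epoch; returned weights
  are those of the best epoch, asserted equal to the history minimum.
* **Arithmetic**: the engine trains in single precision (float32 GEMM via
  the BLAS), matching common deep-learning practice; metrics are computed
  in double precision.
* **Degenerate inputs**: zero training epochs returns the initialised
  network; a non-finite loss aborts with a diagnostic rather than
  returning garbage weights.

## Feature blanking

Importance of feature *f* is measured by replacing every value of *f* in
the test tiles with the test-set pixel mean of *f* and re-evaluating:
ΔRMSE = RMSE(blanked) − RMSE(original). Blanking operates on the raw
feature scale *before* the model's normalizer is applied — "the mean
value observed across all pixels" reads as a raw-data operation, and the
training-fold normalizer then maps that constant wherever the model
expects standardized inputs. ΔRMSE can legitimately be negative when a
feature's observed variation was hurting the model.

## Problem sizes used by the tests and acceptance script

The shipped checks run on fields the package simulates at call time:
a 200 × 200-cell field (1 ha, ≈1 300 tiles, fold B) for the
ranking/denoising/reduced-training checks and the acceptance script, a
400-tile single-signal construction for the importance check, and smaller
grids for unit tests. These sizes were chosen so the full suite trains
its networks under the complete 50-epoch protocol in minutes on one CPU
core; every qualitative property checked (ordering of models, map
smoothness, importance ranking, sub-25 % degradation at 10 % training
data) is scale-free. Hyperparameters are never reduced.

## Known limitations

* The simulator's yield is fully explained by the latent field; absolute
  error levels on simulated data are optimistic relative to real fields.
* Harvester tracks are additive and unobservable from features, acting as
  an irreducible error floor shared by all models; real monitor artifacts
  also correlate with driving speed and moisture.
* The TIFF writer stores no geo-referencing tags; spatial metadata lives
  in the JSON sidecar, so outputs are not drop-in GeoTIFFs for GIS tools.
* Folds assume a roughly rectangular field; heavily masked irregular
  fields can leave some blocks nearly empty (fractions are asserted only
  for grids of at least 20 × 20 tiles).
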
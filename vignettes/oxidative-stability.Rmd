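---
title: "Methods: quantifying antioxidant protection of a fat during storage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying antioxidant protection of a fat during storage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axstab)
```

axstab models a shelf-life experiment in which a carotenoid antioxidant
(astaxanthin, AX) is blended into lard at concentrations of 0-4 mg/g and the
system is followed through accelerated storage (dark, 40 °C) at days 0, 10
and 30. Four instrument-facing analyses are chained together: derivative
spectrophotometry of the pigment, DSC oxidation kinetics of the fat,
second-order response-surface models over (concentration, time), and a
desirability-based choice of the concentration that best balances the four
stability responses. This vignette records the models, the defaults, and the
design decisions behind each stage.

## 1. Derivative spectrophotometry of the pigment

A carotenoid dissolved in a petroleum-ether extract shows a broad absorption
band in the 400-550 nm region. Quantification works on the first-derivative
spectrum dA/dλ, which sharpens the overlapping vibronic structure into two
usable features per analysis window (420-450 nm and 455-480 nm): the maximum
of dA/dλ and the area under the curve (AUC).

`first_derivative()` uses Savitzky-Golay filtering: a local least-squares
polynomial (default order 2, window 11 points = 5 nm on the native 0.5 nm
grid) differentiated analytically, with the filter's one-sided end rows
handling the boundary. The instrument bandwidth implies some smoothing whose
exact form is never published, so the window and order are exposed; the
derivative is exact for polynomial spectra up to the chosen order.

Two readings of "area under the curve for each peak" of a derivative
spectrum are defensible: the integral of the derivative itself (which, by
the fundamental theorem of calculus, is the absorbance difference across the
window) or the integral of the raw absorbance. `extract_features()` defaults
to the derivative integrand and offers `auc_integrand = "absorbance"`; both
are tested. Quadrature is trapezoidal on the native grid — deterministic and
exact for piecewise-linear integrands.

Calibration (`calibrate()`) is ordinary least squares of feature on
concentration, never forced through the origin (real extract calibrations
show small non-zero intercepts, e.g. AUC = 0.2278·[AX] + 0.0302 at day 0).
Pigment loss during storage is summarised two ways: the decline of the
calibration slope with storage day, and a first-order decay fit
ln c(t) = ln c0 − k·t (`fit_first_order_decay()`), the standard kinetic
model for carotenoid degradation. `retention_percent()` reports c(t)/c0
explicitly, because "percent lost" and "percent retained" are easily
conflated in prose; a typical regime here is 5-14 % loss over 30 days
(k ≈ 0.002-0.005 /day).

## 2. DSC oxidation kinetics

Each sample is heated linearly under oxygen at rates β ∈ {5, 7.5, 10, 15}
K/min while heat flow is recorded from 35 to 300 °C. Two quantities are
extracted.

**Onset temperature To.** `detect_onset()` implements the standard tangent
construction — the extrapolated pre-transition baseline intersected with the
tangent at the point of maximum rising slope of the exotherm — plus a
literal "significant deviation" threshold variant (first temperature where
the baseline-subtracted signal exceeds k·SD of the baseline residuals,
k = 10 by default). The tangent method is the default because it is the
construction instrument software uses; the threshold method is retained as
the direct reading of the verbal definition. Slopes are estimated with a
wide local-polynomial derivative (4 × the smoothing window) because a
point-to-point difference quotient on a noisy signal would let single
samples select the tangent point; with 1 % (of peak) noise the tangent To is
reproducible across noise realisations to a fraction of a degree.

**Activation energy by Ozawa-Flynn-Wall.** The isoconversional line is

log10 β = log10(A·Ea/R) − 2.315 − 0.4567·Ea/(R·T),

fit as log10 β = a·(1/T) + b over the heating-rate set, with
Ea = −a·R/0.4567 and A = (R/Ea)·10^(b+2.315). The Doyle constants are
base-10 constants, so the regression is base-10 throughout; temperatures are
converted to kelvin before any 1/T computation and To is reported in °C.
The temperature entering the regression at conversion α is located on each
curve by the partial-area construction (`conversion_curve()`): cumulative
baseline-subtracted exotherm area over total area, clipped to [0,1] and made
non-decreasing. The default conversion level is α = 0.05, early enough to
probe initiation but far enough above the leading tail to be measurable; an
onset-based variant (`alphas = "onset"`) is provided because published work
does not always state which temperature entered the regression.

Numerical care concentrates in the baseline. A linear baseline fit on a
region that overlaps the exotherm's exponential leading tail absorbs early
reaction heat and tilts the subtraction, which biases the low-α temperatures
differently at each β (the tail scales as 1/β) and therefore biases Ea. The
package uses a two-pass fit: a first pass on the lower 30 % of the
temperature range locates the exotherm, then the line is refit on everything
more than 20 °C below the leading edge (defined as the larger of 5 baseline
residual SDs and 0.2 % of the peak deviation). The baseline-subtracted
signal is also lightly Savitzky-Golay smoothed (51 points = 5 K) before
integration so rectified noise does not accumulate as spurious area. With
these defaults, noise-free recovery of a known Ea = 95 kJ/mol from four
simulated curves lands within ~3 % — the residual being the documented bias
of the Doyle approximation at x = Ea/RT ≈ 25 — and the median error over
noisy replicates (2 % of peak) stays under 5 %.

## 3. Response-surface models

Each response Y ∈ {To, Ea, PV, TBA} is fit to the full second-order
polynomial

Y = β0 + β1·X1 + β2·X2 + β3·X1² + β4·X2² + β5·X1·X2,

with X1 = concentration (mg/g) and X2 = time (days) in natural units.
Natural units are the default because the published intercepts match the
(0,0) design-point responses, which is only possible uncoded; a
center-and-scale coding option exists since factor coding is commonly
reported. Inference is standard OLS: t-tests on the residual df per
coefficient, R² = 1 − SSE/SST.

Model-level diagnostics come in two conventions (`diagnostics()`):

* `"conventional"`: df_model = 5, df_error = n − 6; adjusted
  R² = 1 − (1−R²)(n−1)/(n−6); F = (SSR/5)/(SSE/(n−6)); predicted
  R² = 1 − PRESS/SST with leave-one-out PRESS from the hat matrix.
* `"as_published"`: df_model = 1, df_error = n − 2, giving adjusted
  R² = 1 − (1−R²)(n−1)/(n−2) and F = R²(n−2)/(1−R²). Some published panels
  follow this simple-regression convention — for the packaged 24-run table
  it reproduces all four published adjusted R² and F values exactly from
  the reported R² — so it is exposed by name, while `"conventional"` stays
  the default for new analyses.

The lack-of-fit test partitions SSE into pure error (within replicate groups
of identical design points, exact equality by default) and lack of fit; with
no replicates it returns a not-computable flag rather than an error — the
packaged 24-run table has no exact replicates, so its lack of fit is flagged.
Model reduction (`reduce_model()`) is backward elimination, dropping the
least significant term with p > 0.05 one at a time; hierarchy is not
enforced by default (an option enforces it) because the published analyses
drop individual non-significant terms. Group comparisons in the style of
replicate assay tables are served by `tukey_letters()`: one-way ANOVA from
summary statistics, Tukey-Kramer pairwise comparisons on the studentized
range, and an insert-and-absorb compact letter display.

## 4. Desirability optimization and agreement

The four responses are combined with one-sided linear Derringer
desirabilities: maximize To and Ea, minimize PV and TBA, each mapped to
[0,1] with bounds at the response's observed range in the design table,
shape s = 1 and equal weights. The published account names the desirability
approach but gives neither functional form nor bounds, so the most neutral
choices — linear, observed-range, equally weighted — are the defaults, and
all three are configurable. The overall desirability D is the weighted
geometric mean (zero-absorbing). Because a single recommended concentration
"during storage" is wanted, the default profile D(X1) averages D(X1, t)
over the storage days {0, 10, 30}; a fixed-time mode exists. Optimization is
a deterministic grid search on [0, 4] mg/g at 0.01 mg/g (ties break toward
the lower, cheaper concentration); a grid is preferred to a continuous
optimizer because D is cheap, possibly flat near the optimum, and the
profile itself is a deliverable.

On the packaged design table this procedure places the optimum at 1.75 mg/g
(D = 0.51). Readers comparing with the source study should note a data-level
caveat: in the printed 24-run table the TBA response *increases* with
antioxidant concentration at every storage day, while the replicate-level
TBA table in the same study shows the opposite trend from day 10 onward.
With TBA pulling the optimum down and PV pulling it up, the grid optimum is
robustly in the 1.5-1.9 mg/g range under every variant we examined (reduced
models, published coefficients, prediction-range bounds, per-day profiles),
below the 2.5-3.5 mg/g window the study reports from its surface plots. The
package reports what the stated procedure computes from the printed table.

Model validation uses Bland-Altman agreement (`bland_altman()`):
differences experimental − predicted, bias = mean difference, limits of
agreement bias ± 1.96·SD with the n−1 sample SD. For a full OLS model
evaluated on its own training data the bias is exactly zero (residuals of an
intercept model sum to zero), so non-zero biases only appear for reduced
models or held-out data.

## 5. What the synthetic generators emulate — and what they do not

The generators exist so every stage is testable against known ground truth
without instrument data.

* `simulate_spectrum()`: two Gaussian bands (centers 446 and 490 nm,
  σ = 12 nm, heights 0.60 and 0.75 absorbance per mg/g) on a linear
  baseline, with Gaussian noise (default SD 1e-3) and a linear per-day band
  attenuation (0.004/day ≈ 12 % over 30 days). Both band centers sit above
  their analysis windows so every derivative feature grows with
  concentration, matching real extract calibrations; the attenuation
  reproduces the slope-decline pattern across storage days. Real carotenoid
  spectra have asymmetric vibronic structure, solvent shifts and
  concentration-dependent baselines that this model does not attempt; no
  published band shapes or extinction coefficients exist for AX in
  lard-derived petroleum-ether extracts, so these are stated as defaults,
  not fitted values.
* `simulate_dsc_curve()`: an nth-order Arrhenius reaction
  dα/dT = (A/β)·exp(−Ea/RT)·(1−α)^n integrated by fixed-step classical
  RK4 on the 0.1 °C grid (reproducibility is preferred over adaptive
  stepping), rendered as heat flow = height·dα/dT + linear baseline + noise.
  Defaults Ea = 95 kJ/mol, log10 A = 9.3 (min⁻¹) put the exotherm near
  240 °C at 10 K/min, the regime of lard oxidation. First order is the
  default since the isoconversional method does not require an order; n is
  exposed. Real fat oxidation is multi-step with curved baselines — the
  generator makes no attempt at either, which is precisely why the
  isoconversional Ea(α) profile of a simulated set is flat.
* `simulate_design()`: responses from a known quadratic surface plus
  Gaussian noise at the design points of the packaged table. Defaults use
  coefficients and noise SDs representative of the packaged study
  (e.g. To ≈ 238 + 3.2·X1 − 0.66·X1² ..., residual SD 1.68 °C). A noiseless
  simulation followed by a refit is an exact round trip, which anchors the
  fitting code.

Passing tests on these generators therefore demonstrate correctness of the
*computations* under the stated models, not fidelity of the models to any
particular instrument.

## 6. Tolerances, determinism and problem sizes

All randomness flows through explicit seeds; generator calls restore the
caller's RNG state, and pipelines derive per-curve sub-seeds
deterministically from one seed. Spectra use a 350-600 nm grid at 0.5 nm
(501 points); DSC curves 35-300 °C at 0.1 °C (2651 points). The test suite
simulates 4-curve heating-rate sets (50 noisy replicates for the recovery
property), 200-replicate design simulations for OLS unbiasedness and
500-replicate simulations for coefficient-CI coverage (checked within three
Monte-Carlo standard errors of the nominal 95 %); the full suite runs in
well under a minute on one CPU. Degenerate inputs are classed errors, not
NaNs: all-equal calibration concentrations, duplicate OFW temperatures,
rank-deficient designs and zero-slope inversions raise singularity errors;
baselines without an exotherm raise "no onset detected"; windows outside the
grid, non-uniform grids and malformed CSVs raise format/parse errors with
the offending column or row named.

## 7. Known limitations

* The OFW estimate inherits the Doyle approximation's few-percent bias at
  low x = Ea/RT; no iterative Doyle correction or Vyazovkin refinement is
  implemented, and no Kissinger/Friedman alternatives are offered.
* Onset detection assumes a linear pre-transition baseline.
* The desirability machinery is one-sided (maximize/minimize); target-value
  desirabilities and constrained optimizers are out of scope.
* Lack of fit requires exact replicate design points unless a grouping
  tolerance is supplied.
* The spectral model is two-band Gaussian; it cannot be used to claim
  accuracy for real multi-component extracts.
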
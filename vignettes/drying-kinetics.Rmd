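---
title: "Methods: thin-layer drying kinetics, mass transfer and surrogates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thin-layer drying kinetics, mass transfer and surrogates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(drykin)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The physical model

A thin layer of 4 mm slices dries two-sided, so the diffusion half
thickness is `L = 2 mm`. Moisture state is tracked as the dimensionless
moisture ratio `MR = M / M_i` on dry basis; the equilibrium moisture
content is treated as negligible against the initial 85.8% wet-basis
(6.04 dry-basis) load, the standard simplification for high-moisture
produce. Internal diffusion controls the falling-rate period, so Fick's
second law for an infinite slab with uniform initial moisture and
negligible surface resistance gives the series solution

    MR(t) = (8 / pi^2) * sum_{n >= 1} exp(-(2n-1)^2 pi^2 D_eff t / (4 L^2)) / (2n-1)^2.

`fick_series_mr()` implements the standard convergent series over odd
indices `2n - 1`, `n = 1, 2, ...` (a printed variant that starts the index
at zero would double-count the leading term; we treat that as a
typographical slip). Truncation error at `t = 0` is `~0.2 / n_terms`, so
the generator keeps 500 terms by default — enough that the simulated curve
starts within `4e-4` of MR = 1 — while demonstrating full convergence to 1
requires a few hundred thousand terms (cheap at a single time point, and
exercised in the acceptance checks).

## Synthetic experiment generator

The generator defines the study conditions under which everything else is
tested:

- 3 x 3 x 3 factorial grid: 40/50/60 degC, 0.3/0.7/1.0 m/s,
  1500/3500/5500 W/m2; temperature varies slowest, intensity fastest.
- Initial moisture 85.8% wb; curves truncate at the first sample at or
  below 6% wb; 500 g batch; 300 s sampling interval.
- Effective diffusivity: Arrhenius in temperature around a reference of
  `5e-10 m2/s` at (50 degC, 0.7 m/s, 3500 W/m2) with activation energy
  25 kJ/mol (mid-range for vegetable drying), modulated by power laws
  `(IR/IR_ref)^0.25 * (V/V_ref)^-0.15`. The exponents make diffusivity
  increase with infrared intensity and decrease with airflow — the
  qualitative behaviour reported for infrared-convective dryers (radiant
  heating raises the internal moisture gradient; faster air cools the
  slice surface). Across the grid this puts D_eff between roughly 2.8 and
  8.4 x 10^-10 m2/s, inside the 2.6–8.9 x 10^-10 envelope typical of this
  process. Published per-condition diffusivity triples are not always
  monotone in intensity; the generator does not attempt to reproduce any
  specific non-monotone triple.
- Noise: multiplicative lognormal on the mass readings with configurable
  coefficient of variation (a balance-error model, unit mean). Dry mass is
  conserved exactly; moisture and MR are recomputed from the noisy masses.
  Truncation uses the noise-free mean trajectory so replicate curves share
  a time base.
- Quality tables: each metric (water activity, total colour change,
  shrinkage, rehydration, vitamin C retention) follows a linear response
  surface in the coded factors (each level range mapped onto [-1, 1]) plus
  Gaussian noise. Defaults keep noiseless water activity inside
  0.40–0.49, decreasing in intensity and temperature; colour change and
  browning increase with intensity and decrease with airflow; shrinkage
  decreases with intensity; vitamin C retention decreases with temperature
  and intensity. Colour is materialised as CIELAB coordinates by
  displacing a fresh reference (L* = 80, a* = 0, b* = 15) along a fixed
  browning direction (lower L*, higher a*/b*) by the colour-change value,
  so the browning index inherits the colour trend; a separate browning
  surface would overdetermine the three Lab coordinates.

What the generator does **not** emulate: shrinkage-coupled moving-boundary
diffusion, within-run temperature dynamics, moisture-dependent
diffusivity, radiation view factors, or correlated replicate structure.
Passing tests therefore demonstrate the estimators against the stated
Fickian/Arrhenius data-generating process, not against every pathology of
real dryer data.

## Thin-layer fitting

All eleven classical models are fitted by bounded Levenberg–Marquardt
least squares in MR-space (`minpack.lm::nls.lm`), except two that are
linear in their parameters and solved in closed form: Wang–Singh
(quadratic in `t`) and Thomson, which is stated inversely as
`t = a ln(MR) + b (ln MR)^2` and fitted by OLS in t-space. Thomson's
report statistics are computed in MR-space after inverting the quadratic,
so all models share one scale; prediction keeps the non-positive root of
the quadratic in `ln MR`, preferring the root closest to the exponential
trajectory `y = t/a` when both are admissible (that branch is continuous
as `b -> 0`).

Numerical choices:

- Internal time unit is seconds; rate constants are `1/s` (convert to
  `1/min` at presentation if desired — fits are invariant to the unit
  change after the corresponding rescale, which the suite checks).
- Bounds: rate-like constants in `(1e-8, 1) 1/s`, shape `n` in
  `(0.1, 5)`, amplitudes in `(-2, 2)`; Thomson's time-like coefficients
  are effectively unbounded.
- Multi-start: 5 seeded starts per fit. The first sets rate constants from
  the slope of `ln MR` vs `t` (MR readings above 1 are clipped to 1.05 for
  this logarithmic step only), amplitudes at their canonical values
  (summing to 1 for multi-exponential forms so MR(0) = 1) and shape/offset
  terms at identity; the rest jitter it lognormally. The best
  sum-of-squares over starts is kept.
- Convergence: at most 1000 iterations per start, cost tolerances 1e-15,
  so zero-residual problems are driven to machine precision (the suite
  checks exact parameter recovery on noise-free curves).
- Degenerate inputs: constant-MR curves and curves with fewer than
  `n_params + 2` usable points are rejected; non-positive MR readings are
  dropped with a warning; per-cell failures in `fit_all_conditions()` are
  recorded, not fatal.

Goodness of fit uses `R2 = 1 - SSres/SStot`, reduced
`chi2 = SSres/(N - n)` and `RMSE = sqrt(SSres/N)`. A printed variant of
the R² formula circulating for this statistic is algebraically degenerate
(its numerator duplicates both denominator factors, forcing the value 1);
the conventional coefficient of determination is used instead.
`select_best()` ranks by the mean of three ranks (R² descending, χ² and
RMSE ascending), breaking ties by fewer parameters, then name —
information criteria are deliberately out of scope.

**Identifiability of the selection study.** The acceptance study generates
curves from Midilli–Kucuk and asks the three-metric rule to rank it first
under 1% noise. That is only a well-posed question when the generating
shape is identifiable: for near-exponential shapes (`n ~ 1`) a mixture of
three exponentials (Modified Henderson–Pabis) approximates the truth below
the noise floor, wins the R² and RMSE ranks by fitting noise with its two
extra parameters, and the rule cannot distinguish the models even in
principle. Midilli fits to infrared-convective drying report strongly
super-exponential shapes — the published correlation for the shape
exponent has intercept `n = 1.74` — which exponential mixtures cannot
track over two decades of MR. The study therefore uses the
study-representative truth `a = 0.98, k = 3.6e-7 s^-n, n = 1.74,
b = -1e-6`, sampled at the experiment's 300 s interval and truncated at
the 6% wb endpoint.

## Diffusivity and activation energy

The slope method regresses `ln MR` on `t` by OLS inside a moisture-ratio
window, default `0.05 < MR <= 0.8`: early points violate one-term series
validity, late points are noise-dominated. The window is an exposed
argument since practice varies. `D_eff = -slope * 4 L^2 / pi^2`. The
intercept is freely fitted rather than pinned to `ln(8/pi^2)`; its
deviation from that value is reported as a lack-of-fit diagnostic. Note
that with the default window the upper edge still carries some
higher-term curvature (one-term is 0.1%-accurate only below MR ~ 0.45), a
systematic ~0.5% effect on full-series curves; against one-term data the
method is exact, and the residual bias largely cancels across temperatures
in the Arrhenius step.

Activation energy comes from OLS of `ln D_eff` on `1/T` with
`R = 8.314e-3 kJ/(mol K)` and `T` the drying-air temperature in kelvin
(`K = degC + 273.15`): `Ea = -slope * R`, `D0 = exp(intercept)`.
Duplicate temperatures raise a singular-design error; identical
diffusivities legitimately give `Ea = 0`. Per-interval drying rate is the
finite difference of dry-basis moisture over time.

## Quality metrics

Straight implementations of the standard definitions: δE as the CIELAB
Euclidean distance to the fresh reference; browning index via the
chromaticity `X = (a* + 1.75 L*) / (6.645 L* + a* - 3.012 b*)` with a
domain error on a vanishing denominator; shrinkage `1 - V_d/V_0` with the
denominator read as the fresh *volume* (its variable definition) and
swelling flagged rather than rejected; rehydration `W_r/W_d`; vitamin C
retention `V_t/V_0` with values above 1 flagged (the titre symbols are
concentration-like and deliberately typed apart from the shrinkage
volumes, which share a symbol in common notation). Water activity at or
above 0.6 is flagged as microbially unstable; the threshold is exposed.

## Response surfaces

Drying time is regressed linearly on (IR, V, T) and each Midilli–Kucuk
constant quadratically with interaction on (I, V), both by OLS with
rank-deficiency errors on collapsed designs. Published correlations of
this family never state predictor units; the coefficient magnitudes are
only consistent with intensity in kW/m2 (W/m2 would dwarf the intercept),
so surfaces carry explicit unit metadata defaulting to kW/m2 and warn on
negative predicted drying times, the symptom of a unit mismatch.
Temperature enters in degC as printed. The shipped reference surfaces echo
their published R² values (0.919/0.911/0.822/0.80) as documentation; they
are not re-derivable without the underlying raw curves, so nothing asserts
them numerically.

## Neural surrogate and self-organizing map

The multilayer perceptron is written from scratch in matrix algebra
because the training loop itself is part of the method surface: reversed
min-max normalization `X = (x_max - x)/(x_max - x_min)` (the printed
convention; `method = "standard"` gives the conventional direction — the
two differ only by an affine flip and invert exactly), scaled-uniform
fan-in weight initialisation, sigmoid or ReLU hidden layers, a linear
output, minibatch backpropagation with SGD or Adam
(`beta1 = 0.9, beta2 = 0.999`), inverted dropout at training time only,
and a seeded 70/30 train/test split with RMSE and R² reported on the
original scale. Analytic gradients are verified against central finite
differences in the suite. Both architectures discussed for this problem
class (12 neurons over two hidden layers; 2 x 15 with ReLU + Adam at
learning rate 0.01) are expressible through the configuration; neither is
privileged, and no claim is made of reproducing any externally trained
weights. Divergence (non-finite loss) raises a training-failure error with
the loss history attached. 5-fold cross-validation uses seeded disjoint
folds with per-fold normalization bounds computed on the training folds
only.

The Kohonen map uses a 20 x 20 rectangular grid (400 units) trained
online with a Gaussian neighbourhood; learning rate (0.5 to 0.01) and
radius (a third of the grid side down to 0.5) decay linearly across
epochs, which in practice drives the per-epoch quantization error down —
the suite asserts the final value does not exceed the first epoch's across
a 10-seed sweep rather than strict monotonicity, since online updates are
stochastic. Codebook vectors are grouped into 5 clusters by Ward
agglomeration (`stats::hclust`), and data rows inherit the cluster of
their best-matching unit.

## Problem sizes and determinism

The test suite and acceptance script run on deliberately modest problem
sizes chosen to exercise every contract: the full 27-condition grid for
end-to-end counts (297 model fits, 9 Arrhenius cells), 100 seeded
replicates for the noisy-diffusivity and model-selection studies, 20
random draws for the activation-energy round trip, and a 216-row
(27 x 8 replicate) quality table for the surrogate. Every stochastic step
— generator noise, jittered fit starts, train/test splits, weight
initialisation, map training — flows from explicit integer seeds, and
repeated runs are bit-identical.

## Known limitations

- The slope method assumes one-term validity inside its window; strongly
  multi-term curves bias it at the half-percent level (see above).
- Quality surfaces are linear in coded factors; curvature in real quality
  responses is not emulated, so surface-fit R² on synthetic data
  overstates what field data would give.
- The MLP is a small dense regressor; no architecture search beyond the
  configured grid, no uncertainty quantification.
- No moisture-dependent or shrinkage-corrected diffusivity, no spatial
  moisture profiles, no chamber heat-transfer model.
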
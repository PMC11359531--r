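---
title: "Methods: multi-component IVIVC from dissolution to plasma prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-component IVIVC from dissolution to plasma prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivivctk)
```

## The problem

Oral solid preparations that contain several active constituents — the
motivating case is a traditional Chinese medicine tablet with five quality
markers — need dissolution specifications that actually predict in vivo
exposure. A level-A in vitro–in vivo correlation (IVIVC) supplies that link:
deconvolve the oral plasma profile against an IV-derived disposition kernel
to get a cumulative-absorption curve, regress that curve on the fitted in
vitro dissolution curve, and validate the model by convolving back to a
predicted plasma profile and comparing Cmax and AUC. `ivivctk` implements
that workflow end to end, plus the biopharmaceutics classification needed to
decide which components may be pooled, and the content-weighted pooling
itself.

## Containers and units

All time series ride in `time_profile` objects (strictly increasing times,
finite values, a declared value kind). The internal canonical time unit is
**minutes**; hours appear only at I/O and in reported dissolution
parameters, because mean dissolution times are conventionally tabulated in
hours while PK sampling and lag/shift parameters are in minutes.
`resample()` defaults to monotone piecewise-cubic interpolation (pchip) for
cumulative quantities — a cumulative curve interpolated linearly stays
monotone too, but pchip also keeps the shape between sparse samples without
overshoot — and to linear interpolation for concentrations. Extrapolation is
always an error.

## Dose number and BCS class

Solubility classification uses the dose number D0 = (M0/V0)/Cs with V0 =
250 mL. Because there is no maximum-dose monograph for individual
constituents of a multi-component preparation, M0 is the content of the
component in one administration (content per tablet × tablets per dose).
D0 is reported per medium (pH 1.2, 4.5, 6.8) *and* against the minimum
solubility across those media; the final class uses the conservative
minimum-solubility rule. Permeability above 1e-6 cm/s (apparent
permeability from transwell transport, slope of cumulative receiver amount
over time divided by area × donor concentration) counts as high. Censored
solubility values (reported as "> bound") are stored with a flag and the
bound is used, which is conservative for D0.

## Dissolution

Sampling with replacement dilutes the vessel, so cumulative dissolution is
computed as D_n = (C_n·V1 + V2·ΣC_i)/M. Three model families are fitted to
the mean profile (per-vessel fitting is available but off by default, since
the correlation stage consumes one curve per medium):

* Hill: `Finf·t^b / (MDT^b + t^b)`
* Weibull: `Finf·(1 − exp(−((t − tlag)/MDT)^b))`
* Makoid–Banakar: `Fmax·(t/Tmax)^b·exp(b(1 − t/Tmax))`, constant `Fmax`
  past `Tmax`

The plateau is estimated rather than fixed at 1 by default: components of a
partially releasing tablet routinely plateau at 15–90% dissolved, and fixing
the asymptote at 1 misfits every such curve; `finf_fixed = TRUE` restores
the constrained convention. Fitting is Levenberg–Marquardt under bounds with
a deterministic multi-start grid (time-scale starts at the empirical
25/50/75% crossing times, shape starts b ∈ {0.5, 1, 2, 4}, plateau start at
the observed maximum), so no randomness enters the fit. Model selection
maximizes the correlation coefficient of fitted versus observed (Pearson by
default; √(1 − SSR/SST) available) with near-ties (|Δr| < 1e-4) broken by
the smaller AIC. AIC is the least-squares form n·ln(SSR/n) + 2k; on a
noise-free curve SSR → 0 gives AIC → −∞, which is reported as-is (it is the
correct limit and ranks first, as it should). Absolute AIC values are
therefore comparable only within one data set.

## NCA and the unit impulse response

NCA is deliberately minimal: linear-trapezoid AUC0-t anchored at t = 0
(oral profiles start at zero; IV bolus profiles are back-extrapolated to C0
from the first two samples' log-linear slope), λz by log-linear regression
over the post-Tmax window with the best adjusted R² (≥ 3 points), AUC0-inf
= AUC0-t + Clast/λz, reported as `NA` when no terminal window is estimable.
Absolute bioavailability uses dose-corrected **AUC0-t** — that choice
reproduces the study's printed bioavailability figures, while AUC0-inf does
not; both areas are available.

The disposition kernel is a dose-normalized polyexponential with optional
lag, UIR(t) = Σ A_i·exp(−α_i·(t − tlag)). The printed source formula for
this kernel is kinetically anomalous (a growing exponential and an
absorption constant inside an IV disposition); the standard
polyexponential-with-lag form consistent with the tabulated parameter lists
and with deconvolution theory is implemented instead. Fitting is weighted
least squares with the weighting schemes used by pharmacometric practice —
uniform, 1/Y, 1/Y², and iteratively reweighted 1/Ŷ, 1/Ŷ² (two reweighting
passes) — scanned and ranked by AIC on weights normalized to mean one. The
lag is *not* estimated by default: before the first sample a lag trades off
exactly against the amplitudes (A·e^{αt₀} is invariant), so the estimate is
arbitrary on noise-free data and destabilizes the downstream deconvolution
grid; `fit_tlag = TRUE` enables it, bounded by the first sampling time.
Near-coincident rates (within 1e-6 relative) trigger an automatic refit
with one fewer term, flagged on the result.

## Deconvolution

`deconvolve()` discretizes the convolution equation with a staircase input
rate on a uniform grid (default 5 min). The polyexponential kernel is
integrated *exactly* over each interval, so the only discretization error
is the staircase itself; the resulting lower-triangular system is solved by
non-negative least squares (Lawson–Hanson), enforcing that cumulative
absorption never decreases. The cumulative input is normalized by its own
plateau: the correlation stage relates fractions to fractions, and absolute
bioavailability re-enters only at prediction time. A condition-number guard
(κ > 1e10) rejects grids too fine for the data. Observations are placed on
the grid by monotone interpolation; a leading (0, 0) point is assumed for
profiles that start after time zero. The classical Wagner–Nelson estimate
(C + ke·AUC0..t, normalized by ke·AUC0-inf — a form whose plateau is
invariant to a mis-specified ke) is provided as an independent cross-check
and agrees with the numerical route to < 1% on one-compartment data.

## Correlation, prediction, validation

Four nested linear forms relate absorption to dissolution, from plain
scaling (F1) through time scaling (F2), time shift (F3), and baseline
offset (F4). The dissolution argument Tscale·Tvivo − Tshift is evaluated in
minutes against the hour-scale model (zero whenever negative). Forms are
fitted sequentially, each warm-started from the simpler optimum, which
guarantees RSS monotonicity across the nest — the property used to judge
whether extra parameters earn their keep via adjusted R², AIC and SBC.
t_scale driven to its bounds (1e-3, 1e3) flags non-identifiability.

Prediction convolves the input rate — the *analytic* derivative of the
clamped correlation-transformed dissolution curve (no finite-difference
noise), scaled by dose × f_abs — with the UIR on a 1-min staircase grid.
Because the deconvolved curve is plateau-normalized, the fraction ultimately
absorbed is carried separately (from NCA bioavailability of the training
data) rather than folded into AbsScale; parameter values therefore differ
from conventions that fold it in, while predictions do not. Validation
computes the signed prediction error PE% = 100·(pred − obs)/obs for AUC0-t
and Cmax; the model passes when both |PE| ≤ 15% (inclusive). Selection
across media follows the study design: rank media by adjusted correlation,
then require an internal-validation pass, falling through the ranking when
the top medium fails (the situation that motivated the paddle-speed re-scan
in the source study).

## Multi-component integration

Components sharing a BCS class are pooled: dissolution as the
content-weighted convex combination Ct = Σ Wi·Ci with Wi = Ni/ΣN, plasma as
the unweighted sum CT = Σ Cj as the integration formula prescribes (the
surrounding prose mentions a custom weighting, so an optional weights
argument exists, defaulting to 1). The integrated profiles then run through
exactly the same fitting/deconvolution/correlation code path as a single
component; a one-member class reduces to the identity.

## Synthetic data

`ivivc_scenario()` bundles a ground-truth dissolution model per medium, a
polyexponential disposition, first-order (or dissolution-limited) oral
absorption, doses, tablet content and a proportional log-normal noise model.
Dissolution samples are emitted as *measured concentrations* consistent with
the replacement-corrected formula (V1 = 900 mL, V2 = 3 mL), so the
cumulative computation inverts them exactly in the noise-free limit; the
0.1 M HCl grid stops at 180 min to mirror gastric residence. PK uses the
closed-form Bateman solution (exact, including the confluent ka ≈ α limit).
`default_scenarios()` reproduces the magnitudes of the study inputs:
plateaus 0.15–0.9, MDT ~1–3 h, Cmax ~1–50 ng/mL, biexponential class-level
disposition near (0.48, 0.015) h⁻¹, bioavailabilities 1–15%. The default
noise CV is 10%, at the upper end of the assay precision range (1.3–11.4%)
reported for this class of UPLC-MS/MS methods. Every stream is seeded
deterministically from the scenario seed plus a stable label hash, so
reruns are bit-identical.

What the generator does *not* emulate: between-subject variability beyond
i.i.d. proportional noise, nonlinear (saturable) kinetics, gastric-emptying
variability, and pH-dependent solubility mechanics. Passing tests therefore
demonstrate the estimators' correctness and noise robustness under the
stated model, not robustness to structural model misspecification in real
dogs.

## Numerical choices and problem sizes

* Dissolution fits: 9-point grids, ≤ 12 multi-starts, bounded LM, 200
  iterations — milliseconds per fit.
* Deconvolution: 5-min grid over 24 h is a 288-unknown NNLS, well inside a
  second; the 1-min oracle comparisons use 720–1440 unknowns.
* Property experiments run at 50 seeds (dissolution recovery at 2% CV) and
  20 seeds (full-pipeline internal validation at 10% CV), sizes at which the
  medians and pass rates are stable from run to run.
* Ties in model selection: |Δr| < 1e-4 counts as a tie, resolved by AIC;
  exact ties resolve to the first candidate, making selection deterministic.
* Degenerate inputs: insoluble (Cs = 0) components, zero doses, zero
  concentration profiles, non-divisible deconvolution grids and mismatched
  integration grids all raise informative errors rather than propagating
  NaNs.

## Known limitations

Several printed validation cells in the source tables are arithmetically
inconsistent with the PE formula applied to their own printed
predicted/observed pairs (likely per-animal averaging before rounding);
only self-consistent cells are used as numeric references. The printed
per-component UIR tables list amplitudes of 0 at the tabulated precision
for two components, so those amplitudes cannot serve as numeric references
either. Correlation coefficients against in vivo data that exist only as
figures are treated as rank-order, not numeric, references throughout.
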
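---
title: "Methods: visible/near-infrared leaf calibration with leafspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: visible/near-infrared leaf calibration with leafspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafspec)
```

## The calibration problem

A leaf's visible/near-infrared diffuse reflectance spectrum (here 400–1000 nm,
1360 channels) carries chemical information: chlorophyll absorption produces a
valley near 670 nm and the green reflection peak near 559 nm; O–H and N–H
overtones shape the curve between 800 and 1000 nm, with a pronounced peak near
901 nm. A quality indicator measured by wet chemistry — soluble solids content
(SSC, °Brix), gravimetric moisture content (MC, %), or vitamin C (VC, %) — is
regressed on the spectrum, so that future samples can be assessed
non-destructively.

The statistical difficulty is the shape of the data: many more correlated
channels (P ≈ 1360) than samples (N ≈ 180), per-sample multiplicative scatter
from surface and geometry effects, and instrument noise. The package's
workflow addresses each in turn: preprocessing tames scatter and noise,
Kennard–Stone partitioning builds a representative calibration set, wavelength
selection reduces P, and a regularised regression model (PLSR, MLR on the
reduced set, or LS-SVM) does the fitting.

## Reflectance calibration

With sample counts S, dark counts D (source off) and white-reference counts W,
reflectance is computed channel-wise as R = (S − D)/(W − D). The operation is
invariant to a common additive offset and to a common rescaling of all three
count vectors, which the tests assert. Channels where W = D are reported as a
calibration error rather than silently propagated. Negative reflectance
(sample below dark) is kept and counted in a load report: it indicates an
acquisition fault that clipping would hide.

## The seven preprocessing transforms

The method names follow the conventional chemometrics usage; where the
literature leaves the exact formula open, the package fixes one reading and
keeps the seven mutually distinct:

| method | operation | scope | state |
|---|---|---|---|
| MVN | autoscale to mean 0, variance 1 (ddof = 1) | per channel | calibration means/sds |
| Center | subtract mean | per channel | calibration means |
| Nor | min–max rescale to [0, 1] | per spectrum | none |
| MA | uniform moving average, window 5 | per spectrum | none |
| S_G | Savitzky–Golay least-squares smoothing, window 11, order 2 | per spectrum | none |
| SNV | standardise to mean 0, sd 1 (ddof = 1) | per spectrum | none |
| MSC | regress on reference spectrum, invert fitted affine scatter | per spectrum | calibration mean spectrum |

Two conventions hold throughout the package: standard deviations use the
sample convention (denominator N − 1), and column statistics are *fitted* on
calibration data and *applied* to prediction data (`fit_preprocess()` /
`apply_preprocess()`), so prediction rows never contribute statistics.

Numerical details worth knowing:

* **MA edges.** Channel j averages the channels in
  [max(1, j − h), min(P, j + h)], h = (window − 1)/2 — the window truncates at
  the boundary rather than inventing padding values, so constants are
  reproduced exactly and the hand-checkable case ([1, 2, 3, 4], window 3 →
  [1.5, 2, 3, 3.5]) holds.
* **S_G** delegates to `signal::sgolayfilt()`, which reproduces polynomials of
  degree ≤ polyorder exactly, including in the edge frames. Defaults (window
  11, order 2) are conventional for 1360-channel spectra and configurable.
* **Nor on a constant row** cannot be scaled; it maps to zeros with a warning.
  SNV and MVN treat the analogous degeneracies as errors because silently
  producing NaNs would poison downstream fits.
* **SNV and MSC** both collapse the affine family {a·s + b : a > 0} of a fixed
  spectrum s to a single output — this scatter-equivalence is the property
  that makes them scatter corrections, and the test suite asserts it directly.

## Kennard–Stone partitioning

`kennard_stone()` selects calibration samples greedily in Euclidean distance
on the rows of the (by default preprocessed) spectral matrix: first the most
distant pair, then repeatedly the sample maximising the minimum distance to
the already-selected set. All ties break to the lowest sample index, so the
split is a pure function of the matrix. The calibration set therefore covers
the convex hull of the data first, which is why its indicator range envelops
the prediction set's — a property the tests check along the first principal
direction. With N = 180 and ratio r = 3, n_cal = round(N·r/(r+1)) = 135.

The pipeline computes the split on the preprocessed matrix by default
(`order = "preprocess_first"`); a `"split_first"` switch splits on raw spectra
and fits preprocessing on the calibration rows only. The first order matches
common practice where preprocessing is considered part of the spectra; the
second gives the strictest train/test hygiene. Selection and model fitting see
calibration rows only under either order, which the suite asserts by
poisoning prediction rows under a fixed split and checking the selection is
unchanged.

## Wavelength selection

**CARS** (`cars_select()`). Defaults follow the standard recipe: 160
Monte-Carlo iterations, resampling 80 % of the calibration samples, at most 11
PLS factors, 5-fold RMSECV. The forced retention count at iteration i is
round(r_i · P) with r_i = a·e^(−k·i), a = (P/2)^(1/(N−1)),
k = ln(P/2)/(N−1), the unique exponential schedule running from exactly P to
exactly 2 across N iterations. After the forced cut, adaptive reweighted
sampling draws (with replacement, probability ∝ |PLS coefficient|) among the
survivors; the unique draws form the next subset. One fixed, seeded fold
assignment scores every iteration's subset, so the RMSECV trace is comparable
across iterations and its argmin identifies the returned subset. Iterations
whose PLS fit degenerates (all-zero coefficients) are recorded and excluded
from the argmin. PLS factor counts are always capped by what the current draw
supports, so degenerate Monte-Carlo draws cannot crash a run.

**UVE** (`uve_select()`). P artificial noise channels, uniform on
[0, 10⁻¹⁰·max|X|], are appended — small enough never to influence the PLS fit,
while the stability statistic s_j = mean(b_j)/sd(b_j) over the leave-one-out
coefficient ensemble is scale-free, so the noise block remains a valid null
reference. The cutoff is 0.9 × max|s| over the noise block ("threshold 0.9"
read as a fraction of the maximum noise stability; the ensemble is
configurable to k-fold for speed). A channel with zero coefficient sd gets
infinite stability with a warning (it is always kept). If no real channel
clears the cutoff, the single most stable one is returned with a warning,
because an empty selection has no downstream meaning.

**SPA** (`spa_select()`). Chains grow by successive orthogonal projection —
the next variable has the largest residual norm after projecting out the span
of the chain — which by construction yields linearly independent, minimally
collinear subsets (a duplicated column can never join a chain containing its
twin). Chain prefixes are scored by MLR RMSE on an internal 2/3–1/3
Kennard–Stone split of the calibration data, and the subset size is the
*turning point* of the best-RMSE-versus-size curve: the first size whose
relative improvement to the next falls below `knee_tolerance` (default 0.02),
deliberately not the curve minimum. Note that the projection chain is driven
by variable norms, not by the response: SPA presumes that informative
channels carry distinctive variance, which holds for spectral bands but not
for white noise.

## Calibration models

**PLSR** is single-response NIPALS on centered data; for one response the
weight step is closed-form, each factor costing a few matrix–vector products.
Scores are mutually orthogonal, and at full rank the fit coincides with
ordinary least squares — both properties are asserted, as is agreement with an
independent PLS implementation (mixOmics) used purely as a cross-check. The
factor count (Lvs) is user-specified to mirror standard practice;
`n_factors = "cv"` picks the 5-fold RMSECV minimum over 1…min(25, rank)
because no universal selection rule exists.

**MLR** refuses underdetermined problems (P ≥ N) and singular designs,
pointing the user to wavelength selection; `allow_pinv = TRUE` provides the
minimum-norm pseudo-inverse solution explicitly labelled as such, since a
silent pinv would misrepresent what MLR is. This matters in practice: UVE
often retains more channels than there are calibration samples, so
MLR-on-UVE is only computable through that flag.

**LS-SVM** solves the (N+1)-dimensional linear KKT system; the residual of
that solve is stored on the model (`kkt_residual`, asserted < 10⁻⁸) and the
kernel uses σ² as a direct divisor of the squared distance, the convention
under which published width values are in the thousands for spectra of this
scale. `tune_lssvm()` grids (γ, σ²) by seeded k-fold RMSECV; the pipeline's
default σ² grid scales with the median pairwise squared distance of the
calibration matrix so it adapts to preprocessing.

Model persistence writes every numeric as a 17-significant-digit decimal
string — the precision at which IEEE doubles round-trip exactly — so loading a
saved model reproduces predictions bit for bit.

## Evaluation metrics

RC and RP are the Pearson correlations between measured and predicted values
on the calibration and prediction sets. The raw residual-sum ratio
√(Σ(ŷ−y)² / Σ(y−ȳ)²) sometimes written in definitional shorthand for these
coefficients is not bounded by 1 and cannot be the reported statistic; the
package exposes it separately as a diagnostic (`ratio_c`, `ratio_p`) and
reserves RC/RP for the correlation, the universal meaning in this literature.
RMSEC/RMSEP divide by the set size (not N − 1); std_p uses N − 1; RPD =
std_p/RMSEP exactly, with bands poor < 1.5 ≤ fair < 2.0 ≤ excellent. A
perfect prediction makes RPD undefined; `regression_metrics()` flags rather
than fabricates it.

The assay helpers are deliberately small: `moisture_content()` is the
three-weighing oven-drying formula (m₁−m₂)/(m₁−m₀);
`fit_standard_curve()` fits absorbance on concentration by least squares
(replicate wells averaged first) and `concentration_from_absorbance()` inverts
it.

## The synthetic generator

`generate_dataset()` emulates the structure the linear workflow assumes:

* a gentle linear baseline (0.15 → 0.35 reflectance over 400–1000 nm);
* Gaussian bands at 449, 559, 670, 717, 812, 901 nm with signs fixed so that
  559/717/901 are reflection peaks and 449/670/812 absorption valleys;
* an indicator drawn uniformly over the observed field range (SSC 1.48–4.84,
  MC 87.89–97.27, VC 6.33–44.63) and linearly coupled to the band amplitudes
  — a first-order Beer–Lambert-like encoding, which is precisely the structure
  PLSR posits;
* per-sample scatter a·R + b with a log-normal and b normal, then i.i.d.
  channel noise.

Two noise tiers are provided. The *default* tier (scatter sd 0.02, offset sd
0.003, channel noise sd 0.001) keeps the encoded signal dominant: the
reference pipeline (S_G → KS 3:1 → PLSR with 10 factors, N = 180, P = 1360)
attains RP ≥ 0.95 and RPD ≥ 2, demonstrating parameter recovery when the
model family matches the generator. The *degraded* tier (0.08 / 0.015 / 0.05)
was calibrated — by a three-point scan of the channel-noise level — to land
that same pipeline in the 1.5–2.5 RPD band typical of field spectroscopy of
fresh produce, so that threshold logic and interpretation bands are exercised
where they matter.

What the generator does *not* emulate: wavelength-correlated (coloured)
instrument noise, nonlinear indicator–spectrum links, reference-assay error in
the indicator values, temperature/water peak shifts, and the growth-day time
structure of real crops. Passing tests on synthetic data therefore show
correctness of the algorithms and recoverability under the stated model, not
field performance on real leaves.

`generate_raw_acquisition()` fabricates dark/reference/sample count vectors
that invert exactly through `counts_to_reflectance()`, tying the acquisition
arithmetic into the tested loop.

## Problem sizes and determinism

The test suite exercises the full-size problem (180 × 1360) for the reference
pipeline and Kennard–Stone, and scaled-down instances elsewhere: planted-band
selection studies use 100 × 200 with 5 informative bands (ten seeded
replicates), the preprocessing × selector × model grid uses 60 × 200 with all
7 × 3 × 3 combinations, and oracle comparisons use ≤ 10 samples where
exhaustive recomputation is feasible. These sizes were chosen so each property
is tested at the smallest scale at which it is meaningful.

All randomness flows from one root seed through named substreams (synthesis,
Monte-Carlo draws, fold assignments, noise blocks), so every run — including
the CLI and the grid — is bit-reproducible, and re-running a pipeline with the
same config yields byte-identical artifacts.

## Known limitations

* SPA's norm-driven chains are blind to the response; on data whose
  informative variables are not high-variance it will under-perform, by
  construction.
* UVE with leave-one-out on very large P is the slowest selector; the k-fold
  ensemble option trades a small amount of stability resolution for speed.
* The MLR pseudo-inverse path returns the minimum-norm solution, which is not
  a maximum-likelihood estimator in any useful sense; it exists for
  comparability, not recommendation.
* RPD bands are conventions, not inferential statements; near-boundary values
  (e.g. 1.97 vs 2.03) should not be over-interpreted.
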
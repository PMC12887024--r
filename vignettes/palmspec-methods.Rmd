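---
title: "Methods: Raman calibration of palm oil peroxide and iodine values"
author: "palmspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Raman calibration of palm oil peroxide and iodine values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Crude palm oil quality is routinely summarized by two wet-chemistry numbers:
the **peroxide value** (PV, meq O~2~/kg — primary oxidation, measured by
iodometric titration, AOAC 965.33) and the **iodine value** (IV, g I~2~/100 g
— degree of fatty-acid unsaturation, measured by Wijs titration, AOAC
993.20). Both titrations are slow and destructive. Raman spectroscopy sees
the chemistry behind both numbers at once: C–H bending and C=C stretching
bands (1156, 1287, 1442, 1524, 1602, 1657 cm^-1^) track unsaturation, while
the carbonyl region (1748 cm^-1^ and the shoulder out to ~1840 cm^-1^)
tracks oxidation products. `palmspec` implements the full chemometric
workflow that turns a 1024-channel Raman spectrum (500–2000 cm^-1^) into
simultaneous PV and IV predictions: preprocessing, wavelength selection,
calibration modelling, and RPD-based evaluation — plus a synthetic data
generator so that every stage is exercisable and testable offline.

## The synthetic data generator

No public spectral dataset for this problem exists, so `simulate_dataset()`
emulates one. What it reproduces:

* **Reference-value structure.** Five market profiles (AGB, DOM, KAN, MAD,
  MAK) with per-market mean, SD and observed range for PV and IV. Draws are
  truncated normals bounded by the observed ranges. One subtlety: a printed
  mean/SD/range triple is generally *not* attainable by truncating a normal
  with those moments — asymmetric bounds shift the truncated mean (for the
  AGB peroxide profile, by about +0.5 meq O~2~/kg), and a bounded
  distribution cannot always reach the printed SD (the maximum SD of a
  unimodal distribution on a width-6.7 interval is below 2.08). We resolve
  this by solving (via `uniroot` on the closed-form truncated-normal mean)
  for the latent location whose *truncated* mean equals the profile mean,
  keeping the printed SD as the latent scale. The realized mean is then
  exactly right; the realized SD is slightly below the printed value, which
  we accept as the best a truncated normal can do. Truncation is by
  rejection, not clipping, so no probability mass piles up at the bounds.
* **Band structure.** Pseudo-Voigt peaks (70% Gaussian by default; the
  lineshape is a free choice — Raman bands are commonly fit with
  pseudo-Voigt profiles) at the assigned band positions. Band amplitudes
  are *affine* in the reference values: the carbonyl bands (1748, 1800
  cm^-1^) grow with PV, the cis =C–H / C=C bands (1287, 1602, 1657 cm^-1^)
  grow with IV. Couplings (0.02–0.03 amplitude units per unit PV,
  0.006–0.012 per unit IV) were chosen so that the reference-driven
  amplitude variation is comparable to, but clearly above, the channel
  noise after replicate averaging.
* **Background.** A polynomial baseline plus a broad Gaussian fluorescence
  hump (center 1100 cm^-1^, FWHM 900 cm^-1^, amplitude 5 — an order of
  magnitude above the strongest Raman band, as carotenoid fluorescence in
  crude palm oil is). The hump's amplitude, center and width and the
  polynomial coefficients all vary from sample to sample (SDs 1, 20 cm^-1^,
  50 cm^-1^ and 20% respectively): real baselines vary in shape, not just
  scale, and this is what makes derivative preprocessing matter.
* **Measurement.** Three replicate spectra per sample with i.i.d. Gaussian
  channel noise (SD 0.01) are averaged, mirroring triplicate acquisition;
  replicate averaging divides the noise variance by three.
* **Design size.** 40 samples per market, 200 total. The source design
  reports both "50 per market" and "200 total", which are inconsistent
  (5 × 50 = 250); every downstream count (133/67 split) requires 200, so
  200 wins and the per-market count is 40.

What it does **not** emulate: cosmic-ray spikes, instrument response,
wavelength miscalibration, temperature effects, and any nonlinearity of the
concentration–intensity relationship. The last point matters for
interpreting results: because band amplitudes are affine in PV/IV, linear
PLS is *correctly specified* for these data, and the linear and kernel
models outperform random forests here. On the real samples the ordering was
reversed (RF best), presumably reflecting nonlinearities the generator does
not model. Passing tests therefore show that the pipeline recovers known
parameters under the stated conditions — not that any model ranking
generalizes to real spectra.

PV and IV are drawn independently by default. The inverse PV–IV correlation
described for real oils is available (`pv_iv_correlation`), but no
correlation coefficient is reported anywhere we could anchor it to, so the
default is 0.

## Reference chemistry

`peroxide_value()` and `iodine_value()` implement

$$PV = \frac{(S-B) \cdot N \cdot 1000}{W}, \qquad
  IV = \frac{(B-S) \cdot M \cdot 12.69}{W}$$

with S/B the sample/blank titration volumes (mL), N/M the thiosulfate
normality/molarity and W the sample mass (g). The constant 12.69 (iodine
molar mass and unit conversion folded together) is treated as exact.
`titration_from_pv()` / `titration_from_iv()` are the algebraic inverses, so
synthetic titration endpoints and reference values can be generated
consistently; round trips are exact to 1e-10 relative. Negative implied
volumes are errors, not clamped values — they signal impossible titrations.

## Preprocessing

* **Baseline correction**: asymmetric least squares (Eilers–Boelens), the
  de-facto standard for fluorescence-dominated Raman. Defaults λ = 1e5,
  p = 0.01 hug the lower envelope of a 1024-channel spectrum. The method
  was an open choice (no algorithm is named in the source design); AsLS was
  picked for its ubiquity and two-parameter simplicity.
* **Savitzky–Golay** smoothing and 1st/2nd derivatives: window 15,
  polynomial order 3 (typical for 1024-channel Raman; the design is silent
  here). Derivatives are scaled by the grid spacing, so units are intensity
  per (cm^-1^)^m^. Edges use the filter's polynomial fit on the first/last
  window, preserving channel count. SG reproduces polynomials up to the
  filter order exactly — the second derivative of a quadratic comes back
  constant to 1e-8, which the tests use as an oracle.
* **Wavelet denoising**: multilevel periodized orthogonal DWT (Symlet-8,
  level 4), universal threshold \(\hat\sigma\sqrt{2\ln n}\) with
  \(\hat\sigma\) from the MAD of the finest details, soft thresholding by
  default. Written in-package (no wavelet library ships with the supporting
  R stack); at threshold 0 the filter bank reconstructs to ~1e-14 RMS,
  which the tests verify.
* Derivatives are computed on raw spectra by default: the derivative itself
  removes smooth baselines, and this matches the design's use of an
  unprocessed set for modelling. A `derivative_input` switch applies AsLS
  first for users who want both.

## Partitioning and evaluation

Samples split 2:1 into calibration and prediction sets —
`floor(2n/3)`, so 200 samples give exactly 133/67. The default method is
Kennard–Stone (maximin Euclidean distance on the raw spectra), the dominant
deterministic chemometric splitter; rows are canonically ordered by sample
id first so the split is invariant to row order, and ties break to the
lowest index. A seeded random split is available.

Metrics: Rc/Rp are Pearson correlations on the calibration/prediction sets
(the source tables use the symbol R and call it a correlation coefficient);
RMSEC/RMSEP are root-mean-square errors in reference units; RPD is the
prediction-set reference SD (n−1 denominator) divided by RMSEP, classified
as excellent (≥ 3), acceptable ([2, 3)) or limited (< 2). Note that the
published performance tables are not mutually consistent with any single
SD/RMSEP convention (different rows imply different prediction-set SDs);
`palmspec` enforces the standard definition, and every report satisfies
RPD = sd/RMSEP to 1e-12 by construction.

## Wavelength selection

All three selectors run on calibration data only — prediction samples never
influence selection or tuning — and share a compiled SIMPLS engine that
returns cross-validated RMSE for every component count in one pass (the
component count is re-optimized inside every fit, up to 10 by default,
since the published models use 6–10 latent variables depending on subset).

* **CARS** (`cars_select`): 50 Monte-Carlo iterations; each fits PLS on a
  random 80% of the calibration samples, force-retains the top
  \(\lceil r_i p\rceil\) variables by |coefficient| with the exponential
  decay \(r_i = a e^{-ki}\), \(k = \ln(p/2)/(N-1)\), \(a = e^k\) (so
  \(r_1 = 1\), \(r_N = 2/p\)), then resamples among survivors with
  probability proportional to |coefficient| (adaptive reweighted sampling).
  The subset with minimal 5-fold RMSECV across iterations is returned. The
  iteration count is a config choice: the published RMSECV trace bottoms
  out "around the 20th iteration" but no total is stated, and 50 is the
  common default. The retained-count trace is non-increasing by
  construction and ends at exactly 2 variables.
* **UVE** (`uve_select`): appends p noise columns at amplitude 1e-10,
  collects PLS coefficient vectors over leave-one-out resampling (10-fold
  jackknife above 150 samples, bounding cost), computes reliabilities
  \(c_j = \bar b_j / s_{b_j}\), and cuts real variables at the maximum
  |reliability| of the noise block. The canonical noise-augmented
  algorithm is used even though the source text describes UVE loosely as
  "correlation-based screening" — its reliability plot with explicit random
  variables indicates the canonical form.
* **GA** (`ga_select`): binary chromosomes over individual channels (the
  published per-variable counts, 148/140, imply channel-level genes, not
  windowed bands), fitness = −RMSECV, tournament selection, uniform
  crossover (rate 0.5), bit-flip mutation (rate 0.01), elitism 1,
  population 64, 100 generations, 5 runs with sub-seeds derived from the
  master seed; variables selected in ≥ 3/5 run-best chromosomes survive.
  Initialization activates ~10% of genes so early populations already
  resemble plausible subset sizes. Best fitness is non-decreasing within a
  run (elitism), and a fitness cache keyed by chromosome makes repeated
  evaluations free.

`selection_enrichment()` quantifies whether a selection concentrates in a
wavenumber band via the hypergeometric upper tail. On the default synthetic
data all three selectors are strongly enriched (p ≪ 0.01) in 1700–1850
cm^-1^ for PV and 1280–1670 cm^-1^ for IV — by construction, those are the
coupled bands.

## Calibration models

* **PLS** (`fit_pls`): SIMPLS, mean-centering only (channels share units;
  autoscaling would inflate noise channels). At full rank it equals OLS,
  which the tests verify against the normal equations; coefficients also
  agree with an independent NIPALS implementation.
* **ε-SVR** (`fit_svr`): per-variable scaling of the training spectra to
  [−1, 1] → PCA keeping 95% of variance → RBF-kernel ε-SVR (LIBSVM via
  e1071). All transforms are frozen at fit time. The response is
  standardized internally and ε defaults to 0.1 SDs (the design never
  states ε). `grid_search_svr` does exhaustive 5-fold CV over
  C ∈ 2^−4..2^10^, γ ∈ 2^−10..2^4^ plus one factor-2 refinement pass with 5
  points per axis, so optima between powers of two (like a published
  C = 64.25) are expressible; ties break to smallest C then γ. The scaling
  + PCA pipeline is applied to the SVR only — it is described only for the
  SVR in the source — though a flag can disable it.
* **RF** (`fit_rf`): 250 trees, minimum leaf 10 (the stated configuration),
  mtry = ⌊p/3⌋ (the regression convention; unstated in the source),
  bootstrap sampling, seeded. A single fully-pruned tree predicts one
  constant — the mean of its bootstrap sample; with bootstrap resampling
  this is near, not exactly, the training mean.

All models share the `palm_model` S3 surface (predict / print / summary /
fitted / residuals, plus coef for PLS) and a strict column contract:
prediction input must have exactly the training variable count.

## The experiment grid

`run_experiment()` reproduces the 12-model design per parameter: {PLS, SVM,
RF} × {full spectrum, CARS, UVE, GA}, all on one shared Kennard–Stone
partition so rows are paired. SVR hyperparameters are re-tuned per selected
subset (the published response surfaces differ between subsets, implying
per-subset tuning). A master seed derives per-stage sub-seeds by fixed
offsets, making a rerun byte-identical. Failures are recorded per row
without aborting the rest. The preprocessing winner is chosen by PV
prediction RPD (`compare_preprocessing`) and reused for IV, mirroring the
single choice of second-derivative preprocessing for all subsequent
analyses in the source design; `preprocessing = "second_derivative"` is the
default, `"auto"` re-runs the comparison.

Problem sizes used by the test-suite and the acceptance script: module
tests run on reduced datasets (20–40 samples, 128–256 channels, small GA
populations) chosen to exercise every code path in seconds; the end-to-end
recovery check runs the full default design (200 samples × 1024 channels,
GA at its defaults) once per parameter.

## Numerical choices and degenerate inputs

* Ties: component counts break to the smallest; grid-search ties to
  smallest C then γ; CARS coefficient ties to the lowest variable index;
  `which.min`/`which.max` (first minimum) everywhere else.
* A constant response warns and yields a mean-predicting PLS model;
  constant inputs to correlation or RPD are errors, not NAs.
* A zero-variance variable inside the SVR scaler maps to 0 with a warning.
* UVE reliabilities with zero coefficient spread are retained with an
  infinite sentinel and a warning.
* GA selections that miss the frequency threshold fall back to the best
  single run, with a warning.
* Negative rendered intensities (possible under extreme baseline jitter)
  clip to 0 and are counted in an attribute.

## Known limitations

* The generator's affine couplings make linear models look better than they
  would on real oil spectra; see above.
* The published performance tables themselves (Rc/RMSEC/Rp/RMSEP/RPD on the
  real 200 market samples) are not reproducible here because those spectra
  were never deposited; the package reproduces the *design arithmetic*
  (splits, dimensionality percentages, metric definitions, thresholds) and
  demonstrates parameter recovery on its own synthetic data instead.
* Wavelet denoising requires the channel count to be divisible by
  2^level^ (periodized transform); 1024 channels at level 4 always work.
* Kennard–Stone is O(n²) in memory (distance matrix); fine at n = 200.
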
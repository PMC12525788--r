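---
title: "NIRS chemometrics for thymoquinone in intact black cumin seeds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NIRS chemometrics for thymoquinone: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirseed)
```

# The problem

Thymoquinone (TMQ) is the main bioactive compound of black cumin
(*Nigella sativa*) seeds. Reference quantification by solvent extraction
and HPLC is destructive and slow, which limits its use for screening the
hundreds of individual plants a breeding program produces every season.
Near-infrared reflectance spectroscopy (NIRS) offers a non-destructive
alternative: intact seeds are scanned, absorbance is recorded as
log(1/R) on a 2 nm grid from 400 to 2498 nm, and a multivariate
calibration maps the spectrum to the TMQ concentration in mg per g of
seed.

`nirseed` implements that calibration pipeline end to end — spectral
preprocessing, modified partial least squares (MPLS) regression with
grouped cross-validation, multi-season validation and calibration
expansion, truncation-selection predictability, and
wavelength-significance profiling — together with a synthetic
seed-spectra generator that provides ground-truth data for testing every
stage. Because reference seed data sets of this kind are not publicly
deposited, the package's empirical claims are all made, and tested, on
synthetic spectra whose generating truth is known.

# Spectral preprocessing: the math treatment

A *math treatment* is the ordered recipe applied to every spectrum
before regression. The default, written in the conventional
`(d, gap, smooth1, smooth2)` notation, is SNV + detrend + `(2, 5, 5, 1)`
on the 1100–2498 nm window:

1. **Window restriction.** The visible/short-NIR region (400–1100 nm) is
   dominated by seed-coat colour and carries little compositional
   information; it is excluded, leaving 700 grid points.
2. **Standard normal variate (SNV).** Each spectrum is centered and
   scaled to unit standard deviation, removing additive offsets and
   multiplicative scatter caused by particle-size variation.
3. **Detrend.** The least-squares polynomial of degree 2 in wavelength
   is subtracted, removing baseline curvature. We apply detrend to the
   SNV output (the classic sequential SNV–detrend); the two corrections
   are not interchangeable and the order is fixed in the code.
4. **Gap-segment second derivative.** Spectra are smoothed by a centered
   5-point running mean, then the gap difference operator is applied
   twice. The first derivative at point *i* is
   `(x[i+h] − x[i−h]) / (λ[i+h] − λ[i−h])` with `h = ceiling(gap/2)`
   (3 points for the default gap of 5, i.e. stencil points 12 nm apart).
   Derivatives sharpen overlapping absorption bands and remove residual
   baseline; a second-derivative spectrum has a negative lobe at each
   band center.

Numerical choices worth recording:

* **Gap stencil for odd gaps.** A gap of 5 points cannot be split into
  two equal integer offsets; we use symmetric offsets of
  `ceiling(gap/2)` points and scale by the actual stencil distance. The
  absolute derivative scale cancels in regression, but it is documented
  and stable, and the package's quadratic-input test pins it to the
  analytic second derivative.
* **Edges are trimmed, never padded.** Padding would fabricate signal
  exactly where the wavelength-significance analysis reads peaks. The
  default treatment trims 2 (smoothing) + 3 + 3 (two derivative passes)
  points per edge, so 700 window points become 684.
* **`smooth2 = 1` means no second smoothing pass.**
* **Missing values are not permitted inside a spectrum**; the instrument
  family produces dense grids and imputation would distort derivatives
  silently.

# MPLS regression

Calibrations use PLS1 by iterative latent-factor extraction (NIPALS).
X (processed spectra) and y (TMQ) are mean centered; for each factor the
weight vector is the covariance direction `E'f` between the residuals,
scores are the projection, and both residuals are deflated. The
*modified* PLS of Shenk and Westerhaus adds one step: after each factor,
every wavelength's residual column and the y residual are divided by
their standard deviations, so later factors see a reweighted problem in
which wavelengths that are already well explained cannot dominate. The
scale vectors are stored and replayed at prediction time, and
`modified = FALSE` gives textbook PLS1 — which the test suite verifies
against an independent Krylov-subspace closed form to 1e-8.

Because every step is linear in the input spectrum, the whole factor
recursion collapses to an equivalent linear predictor; the package keeps
both representations and checks they agree to 1e-8, which guards
precisely the class of bookkeeping errors (centering applied twice,
scales applied in the wrong order) that factor recursions invite.

Degenerate inputs are handled explicitly: residual standard deviations
below 1e-10 of the initial spectral scale are replaced by 1 before
division (an exact fit must not divide by zero), and factor extraction
stops early when the residual covariance norm is numerically zero.

## Cross-validation and factor selection

Samples are partitioned at random (seeded) into 5 groups of nearly equal
size; each group is predicted by a model fitted on the others, at every
factor count. SECV(f) is the root mean square of the pooled out-of-group
residuals. The selected factor count is the smallest f whose SECV is
within 2% of the curve minimum — a parsimony rule that avoids the
overfitted factor counts a pure minimum rule picks. The 2% threshold
gets an absolute floor of `1e-8 · sd(y)` so that numerically zero SECV
curves (noiseless data) select one factor instead of chasing
1e-16-level noise. A no-signal guard is part of the acceptance tests:
with y independent of X, the cross-validated one-minus-variance-ratio
must stay at chance level.

An optional outlier-elimination pass (remove samples with
`|cv residual|/SECV > 2.5`, refit once) is a common production step in
NIRS practice but is **off by default**: the analyses this package
reproduces do not describe one, and silent sample removal changes every
downstream statistic.

# Statistics

With e = predicted − reference:

* **SEC** (calibration): `sqrt(Σe² / (n − f − 1))` — one degree of
  freedom per factor plus one for centering.
* **SECV** (cross-validation): `sqrt(Σe²/n)` over pooled out-of-group
  residuals, no bias correction.
* **SEP and bias** (external validation): `bias = mean(e)`,
  `SEP = sqrt(Σ(e − bias)²/(n − 1))`. Bias correction is reserved for
  external validation, where a systematic season offset is exactly the
  failure mode of interest.
* **1-VR** (cross-validation analogue of R²):
  `1 − Var(reference − predictions)/Var(reference)` with the population
  variance (divide by n), floored at 0 for reporting. The divisor
  convention is not recoverable from the instrument-software tradition
  this statistic comes from; the package fixes it, documents it, and
  covers it with an exact-value test.
* **R²** (calibration/validation): squared Pearson correlation. For
  bias-corrected predictions it coincides with R² on raw predictions,
  correlation being translation invariant.

# Multi-season validation and calibration expansion

Seed spectra shift between growing seasons (matrix composition, moisture
history, instrument drift), so an equation calibrated on seasons 1–2
shows bias and inflated error on season 3. The pipeline evaluates three
strategies on the target season: (a) validate on 100% of its samples;
(b) move a random 25% into the calibration pool, refit, validate on the
remaining 75%; (c) a 50/50 split. Splits are seeded; one root seed
drives named substreams (simulation / cross-validation / splits), so all
strategies are compared on the same simulated data and two runs of the
pipeline are byte-identical.

# Selection predictability

Breeding programs act on rankings, not concentrations: the top q% of
samples by predicted TMQ are selected. The selection match is the
percentage of the reference-defined top q% captured by the NIRS top q%,
at cutoffs of 5, 10 and 15%. The selected count is
`k = max(1, round(q·n/100))` with half-up rounding (so 5% of 179 selects
9). Ties at the k-th rank are broken deterministically by sample id and
flagged in the report. For strategies (b) and (c) the match is computed
on the held-out samples only — the expansion samples are part of the
equation and selecting them would be circular. A useful null: an
uninformative predictor matches the hypergeometric expectation 100·k/n,
which the tests verify by simulation.

# Wavelength significance

The average second-derivative spectrum of the 50 lowest-TMQ samples is
compared with that of the 50 highest; the per-wavelength standard
deviation between the two averages (`|a − b|/√2`) peaks where the groups
differ most. Peaks are local maxima ranked by height with a minimum
separation of 20 nm between reported peaks — analyte bands in this
region sit ≥ 16 nm apart and a smaller separation double-counts
shoulders of one band. On synthetic data with known injected bands, the
acceptance tests require the top two peaks to land within two grid steps
(±4 nm) of the injected centers in at least 19 of 20 seeds.

# The synthetic study

`synthetic_config()` generates the three-season study the analyses run
on: 288, 313 and 179 samples with season TMQ distributions of mean 7.75
(range 0.68–14.46), 12.00 (1.74–17.30) and 8.75 (1.08–13.49) mg/g.

* **TMQ distribution.** `max − G` with G gamma (shape 5) truncated to
  the season range; the gamma scale is solved by root-finding so the
  truncated mean matches the season target exactly. The reflection gives
  the left-skewed shape expected of a program selecting for high TMQ
  (more mass near the top of the range).
* **Spectra.** Baseline + analyte bands scaled by true TMQ + interferent
  bands + scatter + season offset + iid noise. Analyte bands sit at
  1650 nm and in the 2038–2114 and 2226–2418 nm combination regions
  (2090, 2106, 2228, 2256, 2272, 2294 nm), with amplitudes of order
  5e-4–8e-4 absorbance per mg/g — a minor constituent on a ~0.5 AU
  background. Interferents (oil-like bands at 1726/2308 nm,
  protein-like at 2180 nm, water-like at 1450/1940 nm, positions
  literature-typical) carry log-normal per-sample loadings; they exist
  to make the inverse problem non-trivial, not to claim compositional
  fidelity. Scatter is per-sample multiplicative (SD 5%), additive
  (SD 0.02 AU) and linear-tilt — exactly the terms SNV + detrend are
  designed to remove. iid noise SD is 1.6e-3 AU.
* **Season effects.** Each season adds a spectral offset along its *own*
  two-feature direction (2022 at 2066/1560 nm, 2023 at 2120/1500 nm)
  with per-sample loading `1 + N(0, 1)` times a 5e-3 AU unit. Distinct
  directions matter: a shared direction is learned by the pooled
  two-season calibration and the across-season transfer problem
  disappears. The random per-sample loading is what degrades *precision*
  (not just bias) on the unseen season, which is what calibration
  expansion then repairs.
* **Reference assay.** Reference values are truth + N(0, 0.12) mg/g.
  The 0.12 figure (≈1.4% CV at the study mean) reflects the
  repeatability of an HPLC-UV assay with external standards. It is a
  deliberate design choice: with a much noisier reference, the
  reference-defined top-5% is itself close to random, every strategy's
  selection match collapses toward the hypergeometric floor, and the
  selection analysis cannot distinguish a good calibration from a poor
  one. Validation R² lands in the high-0.7s/0.8s through spectral noise
  instead.

These defaults were fixed after pilot runs of the pooled calibration and
are the study conditions everywhere: in the tests, the acceptance
script and the analysis scripts. At the defaults, the pooled two-season
calibration cross-validates at SECV ≈ 0.9 mg/g (1-VR ≈ 0.93), external
validation on the unseen season gives SEP ≈ 1.1 with a clear negative
bias, expansion with 50% of its samples brings SEP to ≈ 0.85, and the
5% selection match improves with expansion.

What the generator does **not** emulate: radiative-transfer or
particle-size physics, correlated constituent loadings (true covariance
in black cumin seeds is unknown; loadings are independent), instrument
line-shape effects, and the measured spectrum of pure TMQ. Passing
tests therefore show that the pipeline recovers known structure from
plausibly structured spectra — not that it would achieve the same
numbers on any particular instrument or germplasm.

# Problem sizes

The acceptance tests and the acceptance script use 20 replicate studies
at the full design (288/313/179 samples, 700-point window), which runs
in about two minutes; the regression-oracle checks use 50 random 20×50
instances; the unit tests use miniature seasons (tens of samples) that
exercise identical code paths. These sizes are the package's chosen
trade-off between Monte-Carlo stability and a test suite that stays
pleasant to run.

# Known limitations

* MPLS here is the published residual-standardization modification of
  PLS1; the historical instrument-software implementation is proprietary
  and its cross-validation grouping and factor-selection heuristics are
  not claimed identical. `modified = FALSE` is the documented bridge to
  textbook PLS1.
* SECV's divisor (n) and 1-VR's population-variance convention are fixed
  choices among defensible alternatives; comparisons with software using
  n−1 will differ at the third decimal for these sample sizes.
* The selection match at small k is a coarse statistic (k = 4 means 25%
  steps); median behaviour over replicate studies is the meaningful
  summary, and single-study match tables should be read with that
  granularity in mind.
* `read_spectra()` accepts any uniform grid but the analysis assumes
  2 nm spacing when converting gaps to nanometers in its documentation;
  non-2 nm grids are supported arithmetically (the gap is defined in
  data points).
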
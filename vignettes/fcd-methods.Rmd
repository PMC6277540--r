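---
title: "Functional connectivity density mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional connectivity density mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model behind each stage, the parameters that matter and why their
defaults are what they are, what the synthetic cohort does and does not
emulate, and where the design was genuinely open.

## The pipeline in one paragraph

Each subject contributes a 4D BOLD series on a common 3 mm grid, a
gray-matter mask, and six rigid-body motion parameters. Preprocessing is
purely temporal (drop → detrend → band-pass → nuisance regression).
Functional connectivity density (FCD) is the voxelwise count of
suprathreshold Pearson correlations with all other gray-matter voxels,
split four ways by correlation sign at ±0.3 and by Euclidean centre-to-
centre distance at 75 mm. The four maps are smoothed (4 mm FWHM),
z-standardised per subject, compared across groups with a voxelwise GLM
(group contrast plus nuisance covariates), corrected with Gaussian
random-field (GRF) cluster-level theory (voxel p = 0.01, cluster p < 0.05),
and surviving clusters become (a) seeds for Fisher-z functional
connectivity maps and (b) regions whose mean z scores enter
covariate-adjusted partial Pearson correlations with behavioural measures.

## Spatial frame and conventions

Voxel indices are 0-based internally; every reported coordinate is a
millimetre coordinate obtained through the image affine, which is read from
the NIfTI header (sform preferred) and never resampled — all inputs of one
analysis must share a single grid, and this is checked. The in-mask voxel
ordering shared by every stage is R's native column-major scan order (first
axis fastest); a fixture test asserts that masks, series containers and map
extraction all honour it. Sex is coded 0 = female, 1 = male in the subject
table.

## Preprocessing

The four temporal steps run in a fixed order: (1) the first 10 volumes are
discarded (magnetisation equilibration); (2) each voxel's least-squares
line on (1, t) is removed; (3) an ideal rectangular DFT-domain filter keeps
bins with frequency in [0.01, 0.08] Hz and always removes DC — no named
filter family is canonical here, and the ideal filter is exactly testable
bin by bin; (4) nuisance regression projects every voxel onto the
orthogonal complement of [intercept, 6 motion parameters, mean white-matter
signal, mean CSF signal, global mean signal]. The six raw motion parameters
are used without derivative or squared expansions (the simplest reading of
"motion profiles"; an expansion would be a caller-supplied design). Whether
filtering should precede or follow regression is a known ambiguity of the
toolbox lineage; the listed order (filter, then regress) is adopted, and a
regression test asserts that scrambling the order measurably changes the
FCD of data with drift and motion structure, i.e. the order genuinely
matters. Framewise displacement follows Power's formula,
`FD_t = Σ|Δtrans| + 50 mm · Σ|Δrot|`, with FD₁ = 0.

## FCD definitions and numerics

- **Threshold**: a pair contributes iff `r > 0.3` (positive maps) or
  `r < −0.3` (negative maps), strictly. The negative cutoff mirrors the
  positive one — the only symmetric reading.
- **Distance**: "within" means ≤ 75 mm, so a pair at exactly 75.0 mm is
  short-range; the boundary behaviour is tested at machine-adjacent
  distances.
- **Count vs weighted**: the canonical FCD is a binary degree (count
  mode, the default); a weighted mode accumulating |r| is available. Both
  are checked against a brute-force O(N²) oracle; counts must agree bit
  for bit, weighted sums to 1e−12 (floating-point accumulation order).
- **Blocking**: pairwise work is blocked over voxels (default 2048 per
  block) so memory stays O(N·T + N·block); results are independent of the
  block size, and tests assert it.
- **Zero-variance voxels** are excluded from both sides of every pair with
  a warning rather than an error: noise-free phantoms and aggressive
  masks both produce them legitimately.
- **Normalisation order**: smoothing (4 mm FWHM, Gaussian, kernel
  renormalised over in-mask support so nothing bleeds across the mask
  boundary and constants are preserved) is applied to raw maps, then
  per-subject z-standardisation. Whether the original toolboxes
  standardised before or after group statistics is not documented;
  standardising each subject before the GLM makes "FCD z scores"
  well-defined at extraction time, and the un-standardised path remains
  available by simply not calling the z-scoring step.

## Group inference

The subject-level design is [intercept, group indicator, covariates]; the
contrast tests patient − control. Degrees of freedom are n − rank(design)
with all covariates included. Residual smoothness is estimated from the
variance of spatial first differences of voxel-normalised residuals
(FWHM = √(4 ln 2 / λ) voxels per axis), and the resel count is mask volume
over the FWHM product. Cluster-forming uses the one-sided t quantile at
voxel p = 0.01 directly (not a z-converted field — the df-correct quantile
is exact). Cluster p-values follow the classical GRF construction: expected
cluster count from the 3D Euler-characteristic density of a t field,
expected cluster size from the expected suprathreshold volume, size
survival `exp(−β k^{2/3})`, familywise p `1 − exp(−E[m]·P(size ≥ k))`. The
paper-style "both directions from one correction" is implemented as two
independent one-sided passes at voxel p = 0.01 merged into one signed
table, and a test asserts the two-sided pass equals the union of the
one-sided ones. Cluster connectivity defaults to 26 (the common volumetric
default; 6 and 18 are available and oracle-tested). Peaks are the maximal
|t| voxel with lexicographic mm tie-breaking, so outputs are fully
deterministic.

A Monte-Carlo calibration (200 pure-noise two-sample cohorts, 8 + 8
subjects, 24³ mask, 6 mm-smoothed maps) bounds the realised familywise
cluster false-positive rate at nominal 0.05; the measured rate in this
implementation is ~0.03–0.05. The companion recovery study plants a
Cohen's d = 1.5 effect in a 30-voxel block with 16 + 16 subjects and
requires a surviving cluster with Dice > 0.5 against the planted block in
≥ 80% of replicates. The recovery maps are smoothed at 4 mm — the
pipeline's own FCD smoothing scale. This choice matters: at 6 mm on a 24³
grid the GRF expected-cluster count is so large that a 30-voxel cluster
cannot reach familywise significance regardless of its height, which is a
property of the correction, not a defect of the test.

## Brain–behaviour association

Cluster scores are the per-subject mean of the z-scored map over cluster
voxels. Association is partial Pearson: residualise both the score and the
measure on [intercept, covariates], correlate the residuals, and test with
df = n − k − 2. Analyses default to the patient group only (the clinical
convention for symptom correlations), with a pooled option. No multiple-
testing correction is applied by default, matching the uncorrected
reporting convention for these exploratory correlations; a
Benjamini–Hochberg option exists. A rank-based (Spearman) variant is
available behind a flag for abstracts that quote ρ.

## The synthetic cohort

The generator is the pipeline's ground truth, not a fixture. Each block of
voxels shares a latent Gaussian series (weight w); coupled block pairs
share latents through parent→child edges so the latent correlation equals
the coupling exactly; every voxel adds stationary AR(1) noise (marginal SD
`noise_sd`), a linear drift with per-voxel gain, and a motion-coupled
component driven by a simulated random-walk of the six rigid-body
parameters. This is deliberately the *minimum* structure that makes every
preprocessing stage consequential: detrending must remove the drift,
regression must remove the motion leak and global component, and the
band-pass reshapes the noise spectrum.

Defaults and why:

- **Grid 20×32×20 at 3 mm, T = 120, TR = 2 s, 8 + 8 subjects** — the
  desk-scale preset, sized so that the phantom ellipsoid contains
  voxel pairs beyond 75 mm (a smaller grid cannot host a long-range pair
  at all) while a full cohort runs in minutes. The full-scale preset
  (32 + 32 subjects, 240 volumes of which 230 survive the drop) mirrors
  the emulated study design.
- **Baseline coupling 0.28, patient delta +0.30** — with unit block weight
  and noise SD 0.3 the observable correlation is attenuated to
  ≈ coupling/1.09, so the baseline sits just below the 0.3 connectional
  threshold and the patient effect crosses it. In count mode a coupling
  change only alters FCD when it crosses the threshold, so this crossing
  *is* the planted group effect.
- **Coupling jitter SD 0.05** — gives each subject a continuous planted-FCD
  surrogate, which the cognitive score tracks linearly
  (`score = intercept + slope·surrogate + noise`); the default slope is
  set by `slope_for_target_r()` for a population correlation of −0.4,
  the direction and magnitude of the brain–behaviour couplings the
  pipeline is meant to recover.
- **Demographics** are drawn independently of group (confound-free null) so
  covariate adjustment can be tested as inert; a `confounded` switch ages
  the patients for testing the opposite case.

What the phantom does **not** emulate: hemodynamic response convolution,
scanner artifacts (spikes, ghosting, distortion), anatomical variability
and registration error, and spatially structured physiological noise.
Passing tests therefore demonstrate the correctness of the computations
and the calibration of the inference under the stated noise model — not
performance on real scanner data.

## Problem sizes used in the tests

Unit tests run on 6³–8³ phantoms (tens of seconds in total); the
calibration suites use a 24³ mask with 200 null replicates and 25 recovery
replicates, and the end-to-end cohort uses the desk-scale preset. These
sizes were chosen so the full suite and the acceptance script each complete
in minutes on a single CPU while keeping every Monte-Carlo bound
comfortably away from its threshold.

## Known limitations

- The O(N²·T) pairwise engine is exact, not approximate; at full
  gray-matter resolution (~50k voxels) a subject takes minutes, not
  seconds. Blocking bounds memory but not time.
- GRF cluster p-values rely on asymptotic smoothness and threshold
  assumptions; at low smoothness or low df they are conservative here
  (measured FWER below nominal), and the first-difference smoothness
  estimator carries a known small-sample and discretisation bias (within
  ~15% in the tested regimes).
- The ideal band-pass filter has sharp spectral edges and therefore
  temporal ringing; this is the deliberate, testable convention rather
  than a causal filter.
- Slice timing, realignment and spatial normalisation are out of scope:
  inputs are assumed already on a common grid, as post-normalisation data
  would be.
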
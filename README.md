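# fcdmap

Long- and short-range **functional connectivity density (FCD) mapping** for
resting-state fMRI, with Gaussian random-field cluster inference and
covariate-adjusted brain–behaviour correlation — plus a synthetic BOLD
cohort generator that gives every stage of the pipeline a ground truth.

## Who this is for

Researchers analysing voxelwise degree ("hubness") of resting-state BOLD
data, and anyone who wants a fully testable, self-contained implementation
of the classic FCD workflow: temporal cleaning → voxelwise degree maps split
by connection distance and sign → random-field-corrected group comparison →
seed-based connectivity → brain–behaviour association. Because real patient
scans are rarely shareable, the package ships a phantom cohort simulator so
the whole pipeline can be exercised, calibrated and regression-tested
end-to-end on data with known structure.

## The statistic

For every gray-matter voxel $v$ with time series $x_v$, Pearson correlations
$r(v,u)$ are computed against every other gray-matter voxel $u$. With a
connectional threshold of $r_0 = 0.3$ and a distance boundary of 75 mm
(Euclidean, between voxel centres via the image affine), the four maps are

- **lpFCD**(v) = #{u : r(v,u) >  0.3, d(v,u) > 75 mm} (long-range positive)
- **spFCD**(v) = #{u : r(v,u) >  0.3, d(v,u) ≤ 75 mm} (short-range positive)
- **lnFCD**(v) = #{u : r(v,u) < −0.3, d(v,u) > 75 mm} (long-range negative)
- **snFCD**(v) = #{u : r(v,u) < −0.3, d(v,u) ≤ 75 mm} (short-range negative)

(count mode; a weighted mode sums $|r|$ instead). Maps are smoothed with a
4 mm FWHM Gaussian (masked, kernel renormalised) and z-standardised per
subject. Group inference is a voxelwise GLM t contrast with covariates,
corrected by Gaussian random-field cluster-level theory at voxel p = 0.01,
cluster p < 0.05. Associations between cluster-mean z scores and behaviour
are partial Pearson correlations after covariate adjustment.

Preprocessing before FCD follows the standard temporal chain: drop the
first 10 volumes, per-voxel linear detrend, ideal band-pass 0.01–0.08 Hz,
and regression of six motion parameters plus white-matter, CSF and global
mean signals. Head motion is summarised as Power framewise displacement
(50 mm rotation sphere).

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
desk-scale cohort (8 patients + 8 controls, 20×32×20 grid at 3 mm, 120
volumes at TR = 2 s; a coupled block pair 81 mm apart and another 39 mm
apart, with a short-range coupling raised in patients):

```sh
Rscript analysis/01_simulate_cohort.R   # phantom cohort -> scratch/cohort
Rscript analysis/02_preprocess.R        # temporal cleaning
Rscript analysis/03_fcd_maps.R          # four FCD maps per subject
Rscript analysis/04_group_stats.R       # GLM + GRF clusters + seed FC
Rscript analysis/05_association.R       # brain-behaviour correlation
```

Representative output (seed 1):

```
Planted coupled pairs:
     parent     child coupling dist_mm long_range
1 posterior  anterior     0.28 81.2417       TRUE
2  left_par right_par     0.28 39.0000      FALSE

    map df fwhm_mm resels max_abs_t n_clusters
1 lpfcd  9    9.66  125.3     3.728          0
2 spfcd  9    4.50 1236.0     6.193          0
Planted short-range region: patient - control mean z = 0.805

                  roi measure n partial_r p_value
1 planted_short_range   tmt_b 8    0.3333  0.6667
```

Reading this: the generator records which planted block pair is long- vs
short-range ground truth; after the full pipeline the patients' z-scored
short-range FCD over the planted region exceeds the controls' by ~0.8 z
units (the planted direction), while at this deliberately small cohort size
no cluster reaches random-field significance and the ROI–behaviour partial
correlation (8 patients, 2 residual degrees of freedom) is dominated by
sampling noise — group-level detection power and stable correlations at
realistic effect sizes need the larger cohort preset
(`default_cohort_spec("full")`, 32 + 32 subjects). The calibrated power of
the inference itself is established by the test suite's maps-level studies
(planted d = 1.5: 100% cluster recovery; planted partial r = −0.4 at
n = 32: mean recovered −0.41).

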
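Package: fcdmap
Title: Long- and Short-Range Functional Connectivity Density Mapping for
    Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise functional connectivity density (FCD) analysis of
    resting-state BOLD time series. Implements temporal preprocessing
    (initial-volume removal, linear detrending, ideal band-pass filtering,
    nuisance regression, Power framewise displacement), four-way FCD mapping
    (long-/short-range by a 75 mm Euclidean distance split, positive/negative
    by correlation sign at a 0.3 threshold), masked Gaussian smoothing and
    per-subject z-standardisation, voxelwise general-linear-model t maps with
    covariates, Gaussian random-field cluster-level correction, seed-based
    functional connectivity with Fisher r-to-z, and covariate-adjusted partial
    Pearson brain-behaviour correlation. Includes a synthetic BOLD cohort
    generator with planted block-network connectivity, nuisance structure,
    group effects and coupled cognitive scores, so every stage can be tested
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
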
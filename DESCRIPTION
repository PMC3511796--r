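Package: rehopipe
Title: Regional Homogeneity Mapping and Cluster-Extent Inference for
    Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes voxelwise regional homogeneity (ReHo) maps from 4D
    BOLD time series using Kendall's coefficient of concordance over local
    voxel neighborhoods, with the standard resting-state preprocessing
    chain (initial-volume discard, motion quality control, linear
    detrending, ideal band-pass filtering), within-mask standardization
    and Gaussian smoothing.  Group differences are assessed with a
    voxelwise two-sample general linear model with nuisance covariates,
    corrected for multiple comparisons by Monte-Carlo cluster-extent
    simulation, and followed up with partial correlations between
    cluster-mean ReHo and clinical variables.  A seeded synthetic-cohort
    generator produces NIfTI images, motion files and subject tables with
    the statistical structure the analysis assumes, so the whole pipeline
    is testable end to end without access to scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
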
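Package: amyspace
Title: Spatial Association of Amyloid PET Load with Transcriptome and MRI
    Metric Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for cross-modal spatial-association analysis
    of beta-amyloid PET load against transcriptome-atlas and multimodal MRI
    metric maps: SUVR normalisation against a reference region,
    volume-fraction ROI mask resampling with partial-volume thresholding,
    derived metric maps (ReHo, fALFF, weighted degree centrality, diffusion
    tensor FA/MD via weighted linear least squares), per-subject voxel-wise
    Pearson correlation with Fisher transformation, sign-flip permutation
    testing of absolute correlations against a medium effect-size null,
    permutation tests for clinical correlations, Storey false-discovery-rate
    estimation, and correlation-matrix similarity. Ships a synthetic
    multimodal cohort generator with exactly known ground truth so every
    stage is testable without access to the original cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
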
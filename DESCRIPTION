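Package: petrad
Title: Whole-Brain FDG-PET Radiomics and Deep-Learning Dementia Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for discriminating healthy
    controls from dementia patients on whole-brain FDG-PET volumes in a common
    template space: synthetic cohort generation with subtype-specific regional
    hypometabolism, intensity preprocessing (global-mean scaling, Gaussian
    smoothing), single-subject voxel-wise t-maps with cluster-extent filtering,
    3D radiomic feature extraction (79 first-order and 136 texture features over
    six gray-level matrix families), minimum-redundancy maximum-relevance
    feature selection with Pearson-correlation pruning, a feature-input neural
    network and a 3D convolutional network baseline, and the paired comparison
    of their per-subject probability scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
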
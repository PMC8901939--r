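Package: radharmon
Title: Harmonization of CT Radiomic Features Across Acquisition Protocols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for removing acquisition-protocol (batch) effects from CT
    radiomic feature tables. Implements IBSI-style 3D feature extraction
    (isotropic resampling, absolute gray-level discretization, shape,
    histogram, GLCM, GLRLM, NGLDM and GLZLM features), screening of
    acquisition parameters with Kruskal-Wallis tests, batch definition from
    kernel-kVp protocol combinations, cross-sectional ComBat harmonization
    (location/scale model with parametric, nonparametric or no empirical-Bayes
    adjustment), longitudinal ComBat based on per-feature linear mixed models
    with subject random intercepts, and pre/post batch-dependence assessment.
    A synthetic-data module generates feature tables with known injected batch
    effects and small digital phantoms so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
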
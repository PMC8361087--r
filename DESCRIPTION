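Package: phototrait
Title: Weakly Supervised Plant Functional Trait Prediction from Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links species-level plant functional trait distributions (TRY-style
    trait tables) to geolocated citizen-science photographs (GBIF/iNaturalist-style
    occurrence exports), builds image regression datasets with train-only
    min-max normalisation of log10 targets, trains convolutional regressors on
    images alone or fused with bioclimatic predictors, supports truncated-Gaussian
    target augmentation encoding intra-specific trait plasticity, evaluates
    predictions (MAE, NMAE, R squared, cross-validation, ensembles, robustness by
    annotation category), and turns geolocated predictions into gridded trait
    maps by inverse-distance-weighted interpolation with buffer and land masking.
    A synthetic-corpus generator emulates every input so the full pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    geosphere,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
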
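Package: scalehab
Title: Multi-Scale Random Forest Habitat Suitability Models and Niche Overlap
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scale-optimized habitat suitability modelling for sympatric
    species with random forests. Provides a synthetic-landscape generator with
    known ground truth (autocorrelated covariate fields, logistic suitability
    at known focal scales, presence sampling), spatial rarefaction and buffered
    pseudo-absence generation, circular focal-mean and line-density layers over
    a ladder of spatial scales, out-of-bag scale optimization, Model
    Improvement Ratio (MIR) variable selection, suitability mapping with
    AUC/TSS evaluation, climate-scenario projection with stable/gain/loss
    change accounting, and environmental-space niche comparison (Schoener's D,
    Warren's I, equivalency and background randomization tests, PNTI, NECI).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    randomForest,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    MASS
Config/testthat/edition: 3
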
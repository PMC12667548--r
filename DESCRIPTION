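Package: painsig
Title: Brain-Behavior Correlation Mapping and Multivariate Pain
    Sensitivity Signatures
Version: 0.1.0
Authors@R:
    person("painsig", "developers", email = "painsig@example.org",
           role = c("aut", "cre"))
Description: Individual-differences pain neuroimaging analysis: voxelwise
    brain-behavior correlation maps with Benjamini-Hochberg false discovery
    rate control, partial correlations with dataset-wise standardization,
    Steiger's z tests for dependent correlations, family-aware mixed-effects
    mapping, bootstrap estimation of detection probability and minimal sample
    size, LASSO principal-component-regression sensitivity signatures with
    nested cross-validation, virtual-lesion interpretation, treatment-response
    prediction, and a stacking ensemble combining imaging and behavioral
    predictors. Includes a synthetic-cohort generator with full ground truth
    for parameter-recovery testing and minimal NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    glmnet,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
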
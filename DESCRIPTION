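Package: copdct
Title: Quantitative CT Biomarkers and Diagnostic Models for COPD
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extracts three quantitative imaging biomarkers of chronic
    obstructive pulmonary disease (COPD) from paired inspiratory/expiratory
    chest CT volumes -- the emphysema index (percentage of lung voxels below
    -950 HU), the expiratory/inspiratory mean-lung-density ratio
    (air trapping), and Pi10 bronchial wall thickness from ray-cast airway
    cross-sections -- and fits an eight-model logistic diagnostic ladder
    (demographics plus each biomarker combination) with bootstrap optimism
    correction, coefficient shrinkage, optimal-accuracy cutoffs, confusion
    metrics and the Net Reclassification Index. A synthetic-data module
    generates CT phantoms with exact geometric ground truth and subject
    cohorts with a configurable covariate and biomarker structure, so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
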
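Package: badx
Title: Quantitative Ultrasound and Serum MMP-7 Diagnostics for Biliary Atresia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An analysis pipeline for minimally invasive diagnosis of biliary
    atresia in cholestatic infants. Implements quantitative feature extraction
    from grayscale ultrasound regions of interest (intensity normalization to a
    fixed mean and interquartile range, morphological boundary delineation,
    grayscale/size/texture features), an age-stratified serum MMP-7 positivity
    rule, lasso-selected logistic diagnostic models combining both modalities,
    and a diagnostic-accuracy evaluation suite (ROC/AUC with DeLong confidence
    intervals and comparisons, exact binomial confidence intervals for
    sensitivity/specificity/accuracy, calibration curves, subgroup reports).
    Ships a synthetic cohort and speckle-phantom image generator so the whole
    pipeline runs end-to-end without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    glmnet,
    pROC,
    jsonlite,
    png,
    tibble,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
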
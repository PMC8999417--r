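Package: adcphenotype
Title: Radiomic Phenotyping of Kidney Apparent Diffusion Coefficient Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for radiomics-based phenotyping of kidney
    apparent diffusion coefficient (ADC) maps in chronic kidney disease (CKD).
    Generates fully synthetic multi-b-value diffusion-weighted MRI cohorts with
    cortical ROI masks and clinical covariates, fits voxelwise mono-exponential
    ADC maps by log-linear regression, extracts 54 radiomic features (15
    first-order, 23 gray level co-occurrence matrix, 16 gray level run length
    matrix) under fixed-bin-width discretization, and runs the downstream
    statistics: Spearman correlation maps with strength categories,
    normality-routed two-group comparisons, CKD-EPI eGFR and eGFR-slope
    utilities, Z-score + correlation-distance hierarchical clustering with
    Gaussian-mixture BIC selection of the cluster number, and forward-selection
    logistic regression maximizing AUC-ROC for CKD and progression status.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    RNifti,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
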
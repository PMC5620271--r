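Package: ivimdce
Title: IVIM and Extended-Tofts DCE-MRI Simulation, Voxel-Wise Fitting and
    Staging Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates quantitative MRI phantoms and two-group tumor-staging
    cohorts, performs voxel-wise intravoxel incoherent motion (IVIM)
    bi-exponential diffusion fitting with the segmented high-b approach and
    extended-Tofts pharmacokinetic fitting of dynamic contrast-enhanced
    (DCE) series with variable-flip-angle T1 mapping, and runs the
    cohort-level staging statistics: Student's t-tests, ROC analysis with
    Youden cut-offs and likelihood ratios, DeLong paired AUC comparison,
    stepwise logistic regression, and Spearman correlation with Bonferroni
    correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
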
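Package: hepatofat
Title: Liver Fat Quantification from Multi-Echo MRI with Downstream
    Genetic and Proteomic Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and estimation toolkit for quantitative liver-fat
    phenotyping and its downstream statistics. Generates multi-echo
    gradient-echo MR phantoms with known water/fat/field/R2* ground truth,
    estimates proton density fat fraction (PDFF) maps by a three-point
    Dixon method and by iterative least-squares fitting of the full
    water-fat signal model (IDEAL), reports PDFF through a lowest-s.d.
    region-of-interest rule that avoids water-fat swaps, and converts R2*
    to hepatic iron concentration. Companion statistical-genetics and
    proteomics routines cover rank-based inverse normal transformation,
    additive association, a three-group genotype-genotype interaction
    likelihood-ratio test, fixed-effects inverse-variance meta-analysis,
    genetic risk scores, Mendelian randomization, and an elastic-net
    proteomic disease-stage classifier with shadow-feature selection and
    repeated stratified cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    glmnet,
    jsonlite,
    pROC,
    RNifti,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
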
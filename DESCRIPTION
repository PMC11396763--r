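Package: ssmpca
Title: Scaled Subprofile Model PCA for Phenotype-Differentiating Image Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives voxel-wise phenotype-differentiating patterns from groups
    of co-registered 3D scalar images using scaled subprofile modelling with
    principal component analysis (SSM/PCA). Residual profiles are formed by
    subtracting the reference-group grand mean profile, decomposed by PCA in
    subject space, and combined into a single pattern by stepwise-forward
    logistic regression over retained components. Pattern stability is
    assessed by stratified bootstrap resampling and leave-one-out
    cross-validation; subjects are classified by projected pattern-expression
    scores at a Youden-optimal ROC threshold, and two imaging modalities can
    be combined by classification concordance. Includes a synthetic
    brain-phantom cohort generator with a known embedded pattern for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
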
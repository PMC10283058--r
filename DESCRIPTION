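Package: uromics
Title: Urine Multi-Omics Biomarker Discovery and Stepwise Diagnosis of
    Diabetic Kidney Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for urine metabolite fingerprints and
    peptide profiles acquired by laser desorption/ionization mass
    spectrometry in diabetic kidney disease (DKD) cohorts. Provides a
    synthetic-cohort generator with planted stepwise-regulated
    biomarkers and KDIGO-consistent clinical covariates, spectral peak
    picking (S/N > 3 with a sliding-window MAD noise model), m/z
    feature alignment, quantile cubic-spline normalization, platform
    quality control (replicate concordance, intra/inter-batch RSD,
    internal-standard ratio stability), differential feature discovery
    with Benjamini-Hochberg correction and stepwise-feature
    intersection, PCA and orthogonal partial least squares
    discriminant analysis (O-PLS), a seven-algorithm machine-learning
    comparison of single- versus multi-omics prediction, a three-layer
    LASSO diagnostic cascade with grey-zone evaluation, biweight
    midcorrelation networks, and hypergeometric pathway enrichment
    with signed perturbation (JG) scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    class,
    e1071,
    glmnet,
    jsonlite,
    MASS,
    rpart,
    tibble
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
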
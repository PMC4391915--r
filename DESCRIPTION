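Package: vdrevo
Title: Functional Evolution Analysis of Vitamin D Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis pipeline for comparing vitamin D receptor
    (VDR) function across basal vertebrates: dual-luciferase reporter
    normalization, variable-slope sigmoidal concentration-response fitting
    (EC50, E_MAX, 95% CI), one-site saturation-binding fitting (Kd, Bmax),
    one-way ANOVA with Tukey HSD, z-score standardization and hierarchical
    clustering of species by functional-assay profiles with bootstrap
    cluster-stability and driver-coregulator permutation inference, and
    sequence-level characterization (ORF translation, molecular weight,
    pairwise percent-identity tables). Includes generators for synthetic
    assay data with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
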
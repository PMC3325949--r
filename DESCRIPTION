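Package: parkoct
Title: Retinal Layer Morphometry and Diagnostic Rules for Parkinsonian
    Syndromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for spectral-domain optical coherence
    tomography (OCT) retinal layer morphometry in Parkinson's disease and
    the atypical parkinsonian syndromes (multiple system atrophy,
    progressive supranuclear palsy, corticobasal syndrome). Provides
    per-eye cohort data structures with quality-control filtering and
    eye averaging, a synthetic cohort generator parameterized by published
    per-group layer means and standard errors, derived layer features
    (nasal/temporal means, the central outer-nuclear-layer rule, and
    layer-thickness ratios), group comparison statistics (one-way ANOVA
    with Dunnett many-to-one and Tukey all-pairs post-hoc tests, Spearman
    correlation), threshold-rule diagnostic classification with two-by-two
    screening metrics and likelihood-ratio bands, and an exhaustive search
    over single-feature and two-feature conjunction cutoff rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    multcomp,
    mvtnorm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
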
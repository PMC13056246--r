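Package: clonodyn
Title: Peripheral Blood TCR-beta Repertoire Clonal Dynamics and Immune
    Signature Pharmacodynamics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pharmacodynamic analysis of peripheral-blood T-cell
    receptor beta (TCR-beta) CDR3 repertoires from paired baseline and
    on-treatment immunosequencing samples. Provides per-sample diversity
    statistics (Simpson clonality, downsampled richness, productive and
    T-cell fractions), a paired per-clone two-sided binomial
    expansion/contraction test with Benjamini-Hochberg false discovery rate
    control and new-versus-existing clone classification, cohort-level arm
    and response comparisons (one-way ANOVA, pairwise and paired Wilcoxon
    tests, threshold proportions), single-sample gene-set enrichment
    scoring of log2 TPM expression with a two-timepoint random-participant-
    effect slope model, and a seeded synthetic cohort generator emulating a
    multi-arm immunotherapy trial for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
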
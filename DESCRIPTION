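Package: spermchrom
Title: Multivariate Flow-Cytometry Analysis of Boar Sperm Chromatin and Motility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the multivariate assessment of pig sperm chromatin status
    and motility from per-cell measurements. Computes per-sample flow-cytometry
    statistics (SCSA DNA fragmentation and stainability, monobromobimane
    thiol/disulfide indices, chromomycin A3 protamination, 8-oxo-dG oxidative
    damage, and a sperm physiology panel) from gated event tables, derives CASA
    kinematic variables and motility subpopulations by two-stage clustering, and
    provides the downstream statistical layer: factorial linear mixed-effects
    models, FDR-adjusted correlation matrices, variable clustering on Hoeffding's
    D, and standardized PCA with variable contributions and observation
    clustering. Includes a seeded synthetic-data generator that emulates a
    boar-study design (boars x ejaculates x storage days) with known per-sample
    ground truth so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    yaml,
    jsonlite,
    cluster,
    lme4,
    lmerTest,
    emmeans,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
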
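Package: qpcrstrat
Title: Differential Expression and Patient Stratification for Low-Density qPCR Arrays
Version: 0.1.0
Authors@R: person("qpcrstrat", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for TaqMan low-density-array (and similar
    plate-based qPCR) miRNA profiling of small clinical cohorts: censoring of
    undetected cycle-threshold (CT) values, detection filtering, censoring-aware
    quantile normalization, data-driven endogenous-control selection, delta-CT
    and 2^-ddCT differential expression with Benjamini-Hochberg correction,
    hierarchical-clustering-based patient stratification with subgroup
    re-testing, analyte (cytokine) panel comparison, and a Spearman correlation
    screen linking markers to clinical covariates. Includes a seeded synthetic
    cohort generator with a recorded ground truth so that every stage is
    testable without access to patient data, and a command-line pipeline driver
    with a reproducible run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
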
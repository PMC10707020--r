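Package: mitieval
Title: Multi-Trait Mitigation-Effect Evaluation for Deep-Seeding Stress
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comprehensive evaluation of stress-mitigation treatments from
    multi-trait seedling phenotyping experiments. Implements the mitigation
    effect index (MEI) computed per genotype, treatment and trait against
    unstressed and stressed controls, membership-function (min-max)
    normalization of MEIs, and the comprehensive mitigation score U obtained
    by averaging membership values over all traits, with treatment ranking,
    coefficient of variation and optimum-dose selection. Supporting analyses
    cover Pearson trait correlation with significance testing, principal
    component analysis on the trait correlation matrix with eigenvalue-based
    retention, between-group (average-linkage) hierarchical clustering, and
    relative gene-expression quantification from qPCR Ct values by the
    2^-deltaCt method. A seeded synthetic-data generator emulates a
    two-genotype maize deep-seeding serotonin dose-response design, with a
    built-in preset calibrated to published fold-changes, for pipeline
    validation and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
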
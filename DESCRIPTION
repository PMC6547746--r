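Package: twindiscord
Title: Discordant Monozygotic Twin Methylome and Transcriptome Analysis
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for disease-discordant monozygotic twin
    cohorts profiled on 450K-style methylation arrays, EpiTYPER-like
    amplicon assays and RNA-seq. Implements amplicon plate quality
    control with two-step missingness filtering and unit-mean
    imputation, array-level detection and replicate-variance probe
    filtering, epigenetic-age and cell-composition feature extraction,
    mixed-model discordance testing, a cross-set ranked
    magnitude-significance differentially-methylated-probe procedure
    with direction-consistency truncation, within-set delta-beta DMP
    calling, paired longitudinal differential expression with TMM
    normalisation, case-control validation, methylation-expression
    integration and Fisher-exact gene-set enrichment. Ships a
    synthetic-cohort generator with planted truth so every stage is
    testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    lme4,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
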
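Package: xewas
Title: Sex-Aware X Chromosome-Wide DNA Methylation Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analytical framework for X chromosome-wide DNA methylation
    association studies with an exposure such as cigarette smoking. Because X
    chromosome inactivation (XCI) produces hemimethylation in females, many
    X-linked CpG sites are bimodal when sexes are pooled; the package screens
    site modality with Hartigan's dip statistic calibrated against a
    simulation-based empirical null, runs sex-stratified site-wise association
    models with chip/batch and co-twin random effects and cell-composition
    adjustment, partitions site variance into additive genetic, common and
    unique environmental components from MZ/DZ twin pairs, tests
    exposure-discordant MZ pairs, and combines cohorts by fixed-effect
    inverse-variance meta-analysis with Cochran's Q and I-squared
    heterogeneity diagnostics. A synthetic X-methylome generator with known
    ground truth exercises the full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    yaml,
    jsonlite,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
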
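Package: methcortex
Title: Cross-Region DNA Methylation Analysis of Autism Post-Mortem Brain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for Illumina 450K-style DNA methylation
    array studies of brain tissue across multiple regions and diagnostic
    groups (control, idiopathic ASD, dup15q syndrome). Provides probe and
    sample quality control, probe-type stratified quantile normalization,
    empirical-Bayes batch adjustment, reference-based neuronal proportion
    estimation, epigenetic-clock age acceleration, per-probe differential
    methylation by ordinary least squares and donor-random-intercept mixed
    models, spatially correlated differentially methylated region calling by
    Stouffer-Liptak combination with Sidak correction, copy-number
    duplication detection from total array intensity, signed co-methylation
    networks with module eigengenes, and probe-count-controlled gene
    ontology enrichment by logistic regression. A synthetic cohort generator
    with full truth tables makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    sva,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
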
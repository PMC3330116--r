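Package: twinewas
Title: Twin-Cohort Epigenome-Wide Association and Methylation QTL Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of DNA methylation in twin cohorts: probe quality
    control and principal-component covariate screening, twin intraclass
    correlations and Falconer-style methylation heritability, cis methylation QTL
    scans with permutation false discovery rates, epigenome-wide association scans
    for age and age-related phenotypes under a family/zygosity linear mixed model,
    monozygotic-twin discordance analysis, a genotype-methylation-phenotype
    mediation-overlap procedure with a permutation null, and functional annotation
    of differentially methylated positions (co-methylation decay, bootstrap
    annotation enrichment, methylation-expression correlation, replication checks).
    A synthetic twin-cohort generator with ground-truth labels makes the full
    pipeline testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    Rcpp,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
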
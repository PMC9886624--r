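Package: vdgrs
Title: Vitamin D Genetic Risk Scores and Supplementation-Stratified
    Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs a six-variant weighted genetic risk score (GRS) for
    serum 25-hydroxyvitamin D from genotype data, including allele
    harmonization against arbitrary REF/ALT orientations, proxy-variant
    substitution through linkage-disequilibrium allele maps, and the
    standard variant- and sample-level quality-control filters (minor
    allele frequency, Hardy-Weinberg equilibrium, call rate, imputation
    info score). Provides covariate-adjusted linear association models
    with Benjamini-Hochberg false-discovery-rate screening, stratified
    by supplementation status, plus adjusted R-squared comparisons of
    nested models and genotype-distribution chi-square tests. A
    synthetic-cohort generator emulates the statistical structure of a
    population biobank and of a multiple-sclerosis case-control cohort
    (Hardy-Weinberg genotypes, supplementation behaviour with
    group-specific prevalence and log-normal dose, covariate effects, and
    either additive or dose-titration gene-environment structure), so the
    full pipeline is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    vcfR,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
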
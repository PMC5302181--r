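Package: comet
Title: Corrected Overlap and Marginal Enrichment Tests for GWAS Summary
    Statistics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tests whether categories of genetic variants (for example
    functional annotation classes) are enriched for variants associated
    with single traits and for variants shared between traits, using only
    GWAS summary statistics. Per-trait association verdicts are derived
    from approximate Bayes factors; per-trait marginal logistic enrichment
    models supply a log-odds-of-chance-overlap offset for a second-stage
    logistic model of the overlap verdicts, so that shared-variant
    enrichment is corrected for the overlap expected by chance from the
    marginal trait associations alone. Includes greedy LD clumping under a
    joint association metric, a DAVID-style hypergeometric comparator, a
    summary-statistic-level simulation engine, and a replicate-level
    calibration harness (type I error, power, inflation factors, QQ data).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: StatisticalMethod, GenomeWideAssociation, SNP, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'abf.R'
    'comet-fit.R'
    'hypergeom.R'
    'simulate.R'
    'calibrate.R'
    'clump.R'
    'io.R'
    'methods.R'
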
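Package: cnvpgs
Title: Consensus CNV Calling QC and Polygenic Score Cohort Statistics for
    Family-Based Genotyping Studies
Version: 0.1.0
Authors@R:
    person("AAB", "Pipeline Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for family-based SNP-array cohort studies:
    merging fragmented copy-number variant (CNV) calls and intersecting two
    independent callers into consensus calls; intensity-based sample quality
    control and a rule-ordered CNV exclusion cascade with a per-filter audit
    trail; annotation of retained CNVs against cytobands, pathogenic
    neurodevelopmental CNV regions (critical-gene and 80 percent reciprocal
    rules) and curated gene lists; relationship classification from pairwise
    identity-by-descent statistics, sex checks with an inbreeding-based
    rescue rule, Mendelian error rates, principal-component ancestry
    assignment and nearest-neighbour control matching; and polygenic-score
    cohort statistics including group Z-tests, the polygenic transmission
    disequilibrium test, spouse correlation, residualized prediction with
    incremental R-squared, Bonferroni correction and analytic power. A
    synthetic-data module generates every input the pipeline consumes, with
    planted ground truth, so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
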
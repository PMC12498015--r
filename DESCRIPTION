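Package: survpairs
Title: Quartile-Stratified Gene-Pair Survival Screening for Co-Dysregulation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Screens transcriptome-wide cohorts for gene pairs whose combined
    expression dysregulation is associated with patient survival. Candidate
    genes are selected by tumour-versus-normal differential expression
    (Mann-Whitney U) and single-gene survival association (Kaplan-Meier,
    log-rank, observed/expected hazard-ratio band); every gene pair is then
    screened by 5-year cumulative survival across quartiles of one gene
    within the high- and low-expression strata of the other, with trend and
    scenario classification and a bidirectional concordance rule. Selected
    pairs are characterised by correlated-gene discovery, hypergeometric
    gene-set enrichment with Benjamini-Hochberg FDR control, and multi-pair
    overlap sets. A seeded synthetic-cohort generator with planted marginal
    and interaction hazards supports calibration and recovery testing
    without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
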
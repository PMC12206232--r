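Package: mloykit
Title: Quantification of Mosaic Loss of Chromosome Y from Arrays, Digital PCR
    and Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("mloykit", "developers", email = "mloykit@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify mosaic loss of chromosome Y (mLOY) in blood and
    tissue. Implements per-subject mLOY estimation from SNP-array log-R ratios
    (median LRR over X/Y probes, derivative log-ratio spread QC, batch
    adjustment, transformation to percent of cells with Y loss, and a
    noise-derived detection threshold), Poisson-based mLOY estimation from
    digital PCR partition counts, single-cell LOY calling by absence of
    male-specific-region (MSY) transcripts with marker-based cell-type
    annotation and per-type case/control enrichment tests, LOY-associated
    functional statistics (differential expression, binned-control module
    scores, gene-set over-representation, activation regressions), cohort-level
    incidence/survival/lung-function models with bootstrap mediation and a
    male-excess attribution decomposition, and seeded synthetic-data
    generators for every input so each stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
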
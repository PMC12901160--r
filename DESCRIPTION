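Package: sscpgate
Title: Phenotyping and Spatial Statistics for Spatial Single-Cell Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of spatial single-cell proteomics (SSCP)
    experiments exported as per-cell protein intensity tables from multiplexed
    tissue imaging. Implements isotype-control background subtraction,
    host-specific positivity calling, lymphoid-follicle field-of-view
    exclusion, hierarchical marker gating of lamina-propria immune cells into
    B-lineage populations (plasmablasts, CD138+ plasma cells and their
    CD19/CD45 maturation subtypes), per-patient fraction and marker summaries,
    nearest-epithelium distance and cell-density statistics, the nonparametric
    cohort comparisons built on top of them, and a seeded synthetic-tissue
    generator with ground-truth labels so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
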
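Package: clonarch
Title: Cancer Cell Fraction Inference and Driver-Gene Clonality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the cancer cell fraction (CCF) of somatic mutations from
    tumor read counts, sample purity and local absolute copy number via a
    binomial likelihood on a discrete CCF grid, classifies mutations as clonal
    or subclonal, and carries the calls through the downstream analyses used
    in tumor clonal-architecture studies: per-gene clonal/subclonal enrichment
    by permutation with FDR control, association of gene-level clonality with
    clinicopathological variables by exact contingency-table tests, and
    three-group Kaplan-Meier, log-rank and Cox proportional-hazards survival
    modelling with backward stepwise selection and bootstrap stability.
    Includes a synthetic-cohort generator with known ground truth (MAF-style
    mutations, SEG-style copy number, purity and clinical tables) so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
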
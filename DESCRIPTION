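Package: tripathotype
Title: Synovial Pathotype Classification and Three-Way Differential
    Expression for Early Arthritis Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for stratifying early rheumatoid arthritis synovium by
    histological pathotype (lympho-myeloid, diffuse-myeloid, pauci-immune
    fibroid) and analysing bulk RNA-seq against that stratification.
    Implements semiquantitative immunohistochemistry classification rules,
    derivation of cell-lineage marker gene modules from a reference
    expression atlas by tissue-specificity criteria, eigengene (SVD) module
    scoring, three-group negative-binomial differential expression with
    likelihood-ratio and pairwise tests, a polar-coordinate "three-way
    volcano" projection of group effects, module-clinical-trait association
    statistics with compartment concordance, and a synthetic-cohort
    generator with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
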
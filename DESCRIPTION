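Package: dormsig
Title: Late-Recurrence Gene Signature Discovery in Multi-Study Breast
    Cancer Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery-and-validation pipeline for gene signatures of late
    (dormancy-escape) recurrence in breast cancer. Harmonizes multi-study
    probe-level expression matrices by removing cross-study structure
    estimated from invariant control probes, calls ER/PR/HER2 receptor
    status from mRNA with bimodal maximum-likelihood cutoffs anchored on
    partial immunohistochemistry labels, runs genome-scale Cox screens
    under overall/early/late time-window censoring schemes, clusters
    selected probes and samples two-way with true centroid linkage,
    computes subtype-enrichment contingency statistics, discovers
    stromal-activation signatures from paired epithelium/stroma samples,
    and scores first-principal-component metagenes. Ships a synthetic
    multi-study cohort generator that emulates the statistical structure
    every stage assumes, so the whole pipeline is testable without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
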
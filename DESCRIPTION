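Package: natrecur
Title: Paired Tumor and Adjacent-Tissue Proteomic Recurrence Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stratifying postoperative recurrence risk from paired
    tumor and non-tumor adjacent tissue (NAT) proteomes. Implements per-protein
    recurrence screening by maximally selected log-rank cut-points and Cox
    proportional hazards, direction-labelled recurrence-related protein (RRP)
    sets, single-sample gene-set enrichment (ssGSEA) and the DFS score
    (unfavorable minus favorable enrichment), dual-tissue prognostic subtyping,
    over-representation and preranked gene-set enrichment analysis,
    immunohistochemistry composite scoring with dual-tissue stratification, and
    a synthetic paired-cohort generator with planted proportional-hazards
    effects so the full workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    jsonlite,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
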
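Package: bcpanel
Title: Cohort-Level Interpretation of Breast Cancer Panel Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cohort-level interpretation of targeted panel
    sequencing of breast cancer. Provides immunohistochemistry-based
    molecular subtyping, somatic mutation landscape and hotspot statistics,
    Fisher/Benjamini-Hochberg enrichment machinery, aggregation over nine
    canonical oncogenic signalling pathways with mutual-exclusivity and
    co-occurrence analysis, an ACMG evidence-point germline classifier of
    the CharGer family, OncoKB-style clinical actionability tiering, and a
    seeded synthetic cohort generator that emulates the statistical
    structure of a large clinical sequencing cohort so every pipeline stage
    is testable without access to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
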
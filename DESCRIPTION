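Package: evlink
Title: Linkage and Change Tracking Across Preprint and Journal Evidence Sources
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying evidence instability across multiple reports of
    the same intervention study: bibliographic record linkage between preprints
    and journal articles (author, ORCID, byline-order, title and timeline
    features), rule-based classification of changes in reported results,
    abstract conclusions, sample sizes and risk-of-bias-relevant methods
    fields between source versions, and descriptive synthesis (time-to-
    publication survival, conclusion-transition matrices, exposure-normalized
    usage metrics). Includes a synthetic-corpus generator with planted ground
    truth so that every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stringi,
    survival,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
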
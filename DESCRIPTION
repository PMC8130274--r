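Package: odmdr
Title: Metadata Repository with Bottom-Up Standardization for CDISC ODM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale metadata repository engine for clinical study
    metadata in the CDISC Operational Data Model (ODM 1.3) XML format.
    Incoming documents are decomposed into atomic resources (studies,
    protocols, forms, item groups, items, code lists, code list items,
    measurement units), equivalent definitions are aggregated by a
    canonical Merkle hash with occurrence counting, and search results are
    ranked by a tradeoff between query match quality and the logarithm of
    occurrences, so that frequently reused definitions surface as de facto
    ("bottom-up") standards. Includes a resource-oriented JSON API layer,
    evaluation statistics for standard emergence (cumulative occurrence
    curves, top-k occurrence ratios), ordinal Krippendorff's alpha with
    bootstrap confidence intervals for rater-agreement analysis, and a
    seeded synthetic ODM corpus generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    digest,
    jsonlite,
    stringi,
    tibble,
    dplyr,
    ggplot2,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    httpuv,
    withr
Config/testthat/edition: 3
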
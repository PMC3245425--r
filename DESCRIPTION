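Package: taxcat
Title: Taxon Concept Identifiers and Change Detection for Taxonomic
    Checklists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for managing persistent identifiers for taxon concepts
    across editions of a taxonomic checklist.  Reads Darwin-Core-style
    delimited checklist tables, detects concept change between editions by
    comparing per-taxon concept signatures (accepted name, synonyms,
    vernacular names, distribution text and provider identifier; higher-taxon
    lineage above species rank), assigns and retains versioned Life Science
    Identifiers (LSIDs) with UUID object identifiers, maintains a repository
    of typed taxon-concept relationships with inference over congruence and
    inclusion, and generates per-taxon Taxon Concept Schema (TCS) style
    RDF/XML metadata documents.  Includes a deterministic generator of
    synthetic checklist editions with ground-truth change logs for testing
    change-detection behaviour.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cli,
    igraph,
    jsonlite,
    rlang,
    stats,
    stringi,
    tibble,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
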
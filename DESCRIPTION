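Package: microsea
Title: Microbe Set Enrichment Analysis and Microbe-Based Disease Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Over-representation analysis of a list of microbes against
    annotated microbe sets (diseases and body positions) using the exact
    hypergeometric tail test with Bonferroni and Benjamini-Hochberg
    corrections and fold-enrichment statistics, together with a
    microbe-based disease-similarity method that builds signed,
    inverse-disease-frequency-weighted disease vectors from curated
    microbe-disease association records and compares them by cosine
    similarity. Includes GMT-style set-database and association-table
    readers and writers, a seeded synthetic-fixture generator for
    benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
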
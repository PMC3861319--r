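Package: genenorm
Title: Multistage Gene Name Normalization for Biomedical Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps gene and protein mentions in biomedical abstracts to unique
    database identifiers (EntrezGene-style IDs) through a multistage pipeline:
    false-positive pruning of tagged mentions, dictionary matching against a
    synonym lexicon (exact lookup with orthographic variants plus a
    Jaro-Winkler approximate fallback), ambiguity resolution by semantic
    similarity computed as a maximum-weight bipartite assignment (Munkres'
    algorithm) between a gene's EntrezGene metadata fields and the in-abstract
    entity context, and a final gene/protein family-name blacklist filter.
    Includes an identifier-level precision/recall scorer and a synthetic
    corpus generator with planted ambiguity for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    clue,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
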
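Package: ontorecog
Title: Ontology Concept Recognition via Sequence Tagging and
    Character-Level Translation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage pipeline for recognizing mentions of ontology
    concepts in biomedical text. Span detection uses an extended BIO(-)
    token tag scheme that captures discontinuous and overlapping mentions,
    with a linear-chain conditional random field detector featuring
    randomized L1/L2 regularization search and cross-validated evaluation.
    Concept normalization is recast as character-level sequence
    translation from mention text to ontology class identifiers using a
    small attention encoder-decoder, alongside a dictionary-lookup
    baseline, class-identifier transformation experiments (shuffled,
    random, alphabetical identifiers), and evaluation metrics including
    character-level partial credit and Jaccard span matching. Readers and
    writers for OBO ontology files and brat-style standoff annotations,
    plus seeded synthetic ontology and corpus generators, make the whole
    pipeline exercisable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
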
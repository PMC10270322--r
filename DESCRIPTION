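Package: adrner
Title: Named Entity Recognition for Adverse Drug Reactions in Chinese Drug Descriptions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A character-level named-entity-recognition toolkit for
    pharmacovigilance text mining. Builds BIO-annotated corpora from raw
    Chinese drug-description records by distant supervision against typed
    lexicons of drug names (DRN), drug components (COM) and adverse drug
    reactions (ADR); implements a neural sequence labeler assembled from
    a character embedding layer, an optional transformer-style encoder with
    ALBERT-type parameter reduction (factorized embedding, cross-layer
    parameter sharing), a bidirectional LSTM context encoder and a
    linear-chain conditional random field label decoder; trains the model
    end to end with Adam and exact CRF gradients; and scores predictions
    with entity-level precision, recall and F1 per entity type and
    micro-averaged.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
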
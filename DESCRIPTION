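Package: patientlens
Title: Social-Media Listening NLP Pipeline for Patient-Focused Drug
    Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: An offline-runnable natural-language-processing pipeline for
    mining patient, caregiver and community perspectives on a disease from
    social-media posts.  Provides sentence-level corpus ingestion with
    deduplication and pseudonymization, lexicon/ontology-based biomedical
    named-entity recognition with precision filters, temporal expression
    extraction with onset day-offset normalization, zero-shot detection of
    abstract entities (needs, support, diagnosis, misdiagnosis) via
    entailment screening plus extractive question answering, hypothesis
    template based zero-shot relation extraction with ontological pruning
    and cue-word demotion, few-shot interest-group classification, and a
    gold-annotated synthetic corpus generator with oracle backends for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    igraph,
    jsonlite,
    nnet,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
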
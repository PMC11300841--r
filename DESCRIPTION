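Package: mirdex
Title: Extraction of miRNA-Disease Associations from Biomedical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A sentence-level text-mining pipeline that extracts normalized
    microRNA (miRNA)-disease associations from biomedical literature. The
    package combines rule-based miRNA mention detection and miRBase
    normalization, trainable IOB sequence tagging and dictionary-based MeSH
    disease linking, distant-supervision corpus construction from
    knowledge-base triples, entity-masked sentence classification with
    single-task or multi-task heads over a shared small trainable encoder,
    threshold-free evaluation metrics (AUROC, average precision, entity-level
    precision/recall/F1) with stratified cross-validation, and
    large-collection inference with confidence filtering and novelty
    comparison against a reference association database via disease-ontology
    subclass expansion. A synthetic-fixture generator provides fully
    reproducible corpora, lexicons and knowledge bases with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
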
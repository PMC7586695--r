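Package: ctxrel
Title: Context-Specific Molecular Relation Extraction from Biomedical Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A literature-mining pipeline that classifies sentences into
    context-specific molecular relation classes (Increase, Decrease, Regulate,
    Binding, each with textual directionality, plus a False class) by combining
    three representation modalities: n-gram skip-gram word embeddings,
    dependency-based word embeddings, and knowledge-graph triple embeddings
    trained with a convolutional scorer that generalizes translational
    embeddings. The classifier is a multi-group norm-constraint convolutional
    network over the three embedding groups, trained by pre-training on
    context-free relation corpora and fine-tuning on a context-specific corpus.
    Includes BioNLP-ST standoff conversion with nested-event decomposition,
    dictionary entity recognition with semantic-group filtering, a
    frequency-threshold and majority-voting post-processing stage, synthetic
    data generators for every stage, and micro-F1 cross-validation with an
    ablation runner over the representation groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
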
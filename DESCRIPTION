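Package: kgner
Title: Knowledge-Graph-Augmented Biomedical Named Entity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A sequence-labeling toolkit for biomedical named entity
    recognition that augments token representations with external
    dependency knowledge. Sentences are matched against a knowledge graph
    of drugs, diseases and targets; matched entities and their
    dependencies form a per-sentence subgraph over which a multi-head
    graph attention layer propagates information; updated node embeddings
    are fused with contextual token embeddings and decoded with an exact
    linear-chain conditional random field. Includes BIO tag utilities,
    CoNLL and edge-list readers and writers, entity- and token-level
    precision/recall/F1 evaluation, a gazetteer baseline, and a synthetic
    corpus/knowledge-graph generator with controllable ambiguity so the
    value of the knowledge pathway can be tested end to end without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
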
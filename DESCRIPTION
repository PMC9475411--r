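Package: ohcinfluence
Title: Influence Relationship Identification in Online Health Community Threads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies influence relationships in decision-making discussion
    threads of online health communities. Builds reply trees from indent-annotated
    posts, enumerates (initial post, reply, counter-reply) triples, measures text
    relevance of post pairs with representation-based (ARC-I style) and
    interaction-based (MatchPyramid style) neural matchers over corpus-trained
    word embeddings, detects question presence with question-mark and constrained
    5W1H rules and future-action presence with modal/future-tense rules, and
    classifies triples as influence relationships with either a product-threshold
    baseline or a deep feature-fusion network trained with binary cross-entropy
    and Adam. Ships a synthetic thread generator, an evaluation harness
    (precision, recall, F1, accuracy, ROC AUC, PR AUC), and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
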
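Package: bayesannot
Title: Ontology-Based Multi-Label Annotation of Abstracts with Naive Bayes Decision Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic annotation of scientific abstracts with labels from a
    flat category/label ontology schema. Implements per-category multi-label
    naive Bayes classifiers under binary relevance, Bayesian Decision Trees
    that restrict each node's training set to documents carrying all ancestor
    labels, and the human-in-the-loop Constrained Decision Tree whose root
    labels are supplied by an expert. Evaluation uses F1-micro under seeded
    k-fold cross-validation, with per-tree score aggregation across all
    category orderings. Includes a synthetic-corpus generator emulating
    ontology-annotated abstract collections with cross-category label
    entailments, plus TSV/JSON corpus input/output and a command-line
    interface.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
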
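test_that("the default schema has the intended cardinality profile", {
  sch <- default_schema()
  counts <- n_labels(sch)
  expect_equal(counts$n_labels[match(c("SM", "ST", "RM", "RT", "I"),
                                     counts$category)],
               c(6, 25, 5, 6, 40))
  # every restriction references existing labels (onto_schema validates,
  # but assert the cross-category direction too)
  expect_true(all(sch$restrictions$if_category != sch$restrictions$then_category))
})

test_that("generation is deterministic in the seed", {
  cfg <- sim_config(n_docs = 30, seed = 77)
  a1 <- sample_annotations(cfg)
  a2 <- sample_annotations(cfg)
  expect_identical(a1, a2)
  t1 <- sample_texts(a1, cfg)
  t2 <- sample_texts(a1, cfg)
  expect_identical(t1, t2)
  a3 <- sample_annotations(sim_config(n_docs = 30, seed = 78))
  expect_false(identical(a1, a3))
})

test_that("full dependency strength forbids restriction violations", {
  cfg <- sim_config(n_docs = 400, dependency_strength = 1, seed = 13)
  ann <- sample_annotations(cfg)
  expect_equal(nrow(restriction_violations(ann, cfg$schema)), 0L)
  # every document is annotated in every category
  per_doc <- dplyr::count(dplyr::distinct(ann, id, category), id)
  expect_true(all(per_doc$n == length(cfg$schema$categories)))
})

test_that("zero dependency strength gives independent categories", {
  cfg <- sim_config(n_docs = 2000, dependency_strength = 0, seed = 13)
  ann <- sample_annotations(cfg)
  has <- function(cat, lab) {
    ids <- unique(ann$id)
    ids %in% ann$id[ann$category == cat & ann$label == lab]
  }
  # the generator's strongest entailment pair shows no association
  tab <- table(has("ST", "Tone"), has("SM", "Auditory"))
  # simulate the null distribution: cell counts are small for rare labels
  p <- stats::chisq.test(tab, simulate.p.value = TRUE, B = 2000)$p.value
  expect_gt(p, 0.05)
})

test_that("labels-per-category means hit their configured targets", {
  cfg <- sim_config(n_docs = 2000, seed = 19)
  ann <- sample_annotations(cfg)
  means <- dplyr::count(ann, id, category) |>
    dplyr::group_by(category) |>
    dplyr::summarise(m = mean(n))
  for (cc in cfg$schema$categories) {
    expect_lt(abs(means$m[means$category == cc] - cfg$mean_labels[[cc]]),
              0.1)
  }
  expect_true(all(cfg$mean_labels >= 1.15 & cfg$mean_labels <= 1.85))
})

test_that("the degenerate mixture uses only the labels' signature words", {
  sch <- default_schema()
  cfg <- sim_config(
    n_docs = 10, background_mix = 0, signature_share = 0,
    mean_labels = stats::setNames(rep(1, 5), sch$categories), seed = 3
  )
  sim <- simulate_corpus(cfg)
  sig <- label_signature(sch, cfg$vocab_per_label)
  key <- paste(sig$category, sig$label, sep = ":")
  for (i in seq_len(nrow(sim$documents))) {
    doc_id <- sim$documents$id[i]
    labs <- sim$annotations[sim$annotations$id == doc_id, ]
    allowed <- sig$word[key %in% paste(labs$category, labs$label, sep = ":")]
    toks <- unique(tokenize(sim$documents$text[i])[[1]])
    expect_true(all(toks %in% allowed))
  }
})

test_that("signature sharing pairs labels symmetrically", {
  sch <- default_schema()
  sig <- label_signature(sch, 4, signature_share = 0.5)
  shared <- sig[grepl("pair", sig$word), ]
  # each shared word belongs to exactly two labels of one category
  per_word <- dplyr::count(shared, word)
  expect_true(all(per_word$n == 2))
  # and the number of private words per label is vocab_per_label - shared
  priv <- dplyr::count(sig[!grepl("pair", sig$word), ], category, label)
  expect_true(all(priv$n %in% c(2, 4))) # 4 for odd-inventory leftovers
})

test_that("fitted conditionals approach the generative word probabilities", {
  cfg <- sim_config(n_docs = 2000, seed = 23)
  sim <- simulate_corpus(cfg)
  vocab <- build_vocabulary(sim$documents)
  x <- featurize(sim$documents, vocab)
  expected <- expected_signature_probability(sim$annotations, cfg)
  sig <- label_signature(cfg$schema, cfg$vocab_per_label,
                         cfg$signature_share)
  sig <- sig[!grepl("pair", sig$word), ] # private words only
  worst <- 0
  for (cc in cfg$schema$categories) {
    m <- nb_fit(sim$annotations, x, cc, cfg$schema)
    rows <- sig[sig$category == cc & sig$word %in% vocab$features, ]
    rows <- rows[rows$label %in%
                   expected$label[expected$category == cc], ]
    est <- m$p_true_given_label[cbind(rows$label, rows$word)]
    truth <- expected$prob[match(
      paste(cc, rows$label),
      paste(expected$category, expected$label)
    )]
    # assess convergence only where the positive-document count keeps the
    # binomial standard error well inside the tolerance
    keep <- expected$n_docs[match(
      paste(cc, rows$label),
      paste(expected$category, expected$label)
    )] >= 400
    if (any(keep)) worst <- max(worst, abs(est - truth)[keep])
  }
  expect_lt(worst, 0.1)
})

test_that("written corpora round-trip and record provenance", {
  sim <- simulate_corpus(sim_config(n_docs = 25, seed = 2))
  dir <- withr::local_tempdir()
  paths <- write_corpus(sim, dir)
  expect_true(file.exists(paths[["provenance"]]))
  prov <- jsonlite::read_json(paths[["provenance"]])
  expect_equal(prov$seed, 2)
  expect_equal(prov$n_docs, 25)
  back <- load_corpus(paths[["documents"]], paths[["annotations"]],
                      paths[["schema"]])
  expect_equal(back$documents, sim$documents)
  expect_equal(
    dplyr::arrange(back$annotations, id, category, label),
    dplyr::arrange(sim$annotations, id, category, label)
  )
})

test_that("cyclic restriction graphs are rejected", {
  sch <- onto_schema(
    c("A", "B"),
    list(A = c("a1", "a2"), B = c("b1", "b2")),
    restrictions = data.frame(
      if_label = c("a1", "b1"), if_category = c("A", "B"),
      then_label = c("b1", "a1"), then_category = c("B", "A")
    )
  )
  cfg <- sim_config(schema = sch, n_docs = 5,
                    mean_labels = c(A = 1.2, B = 1.2), seed = 1)
  expect_error(sample_annotations(cfg), "cycle")
})
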
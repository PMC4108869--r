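test_that("ordering enumeration yields exactly k! distinct permutations", {
  for (k in 2:4) {
    ords <- category_orderings(paste0("C", seq_len(k)))
    expect_length(ords, factorial(k))
    expect_equal(length(unique(vapply(ords, paste, "", collapse = ">"))),
                 factorial(k))
    expect_true(all(vapply(ords, function(o) {
      setequal(o, paste0("C", seq_len(k)))
    }, logical(1))))
  }
})

toy_cache <- function() {
  tc <- toy_corpus()
  v <- build_vocabulary(tc$documents)
  x <- featurize(tc$documents, v)
  list(
    cache = bdt_cache(tc$annotations, x, tc$schema),
    x = x, tc = tc
  )
}

test_that("a depth-1 tree reproduces the flat classifier exactly", {
  tt <- toy_cache()
  tree <- bdt("ST", cache = tt$cache)
  pred <- classify(tree, tt$x)
  flat_model <- nb_fit(tt$tc$annotations, tt$x, "ST", tt$tc$schema)
  flat <- predict_labels(flat_model, tt$x)[, c("id", "category", "label")]
  expect_equal(
    dplyr::arrange(pred, id, label),
    dplyr::arrange(flat, id, label)
  )
})

test_that("node training sets are restricted by the ancestor labels", {
  tt <- toy_cache()
  tree <- bdt(c("SM", "ST"), cache = tt$cache)
  pred <- classify(tree, tt$x)
  # hand-traced traversal: auditory docs get SM Auditory then ST Tone,
  # visual docs SM Visual then ST Picture
  expect_equal(
    pred$label[pred$id == "d1"][order(pred$category[pred$id == "d1"])],
    c("Auditory", "Tone")
  )
  expect_equal(
    sort(pred$label[pred$id == "d5"]),
    c("Picture", "Visual")
  )
  nodes <- tree_nodes(tree)
  aud <- nodes[vapply(nodes$ancestors, identical, logical(1),
                      "SM:Auditory"), ]
  expect_equal(aud$n_train, 4) # 4 of the 6 toy docs are auditory
  # restriction soundness: every training document's gold labels contain
  # the full ancestor set
  gold_sets <- split(
    paste(tt$tc$annotations$category, tt$tc$annotations$label, sep = ":"),
    tt$tc$annotations$id
  )
  for (i in seq_len(nrow(nodes))) {
    anc <- nodes$ancestors[[i]]
    for (d in nodes$training_ids[[i]]) {
      expect_true(all(anc %in% gold_sets[[d]]))
    }
  }
})

test_that("a silent root truncates the traversal", {
  tt <- toy_cache()
  # cutoff above every posterior: nothing is predicted anywhere
  tree <- bdt(c("SM", "ST"),
              policy = threshold_policy(alpha = 0.999999),
              cache = bdt_cache(tt$tc$annotations, tt$x, tt$tc$schema))
  pred <- classify(tree, tt$x)
  expect_equal(nrow(pred), 0L)
})

test_that("degenerate orderings are rejected", {
  tt <- toy_cache()
  expect_error(bdt(character(0), cache = tt$cache), "at least one")
  expect_error(bdt(c("SM", "SM"), cache = tt$cache), "distinct")
  expect_error(bdt("XX", cache = tt$cache), "distinct")
})

test_that("the constrained tree takes its root from the oracle", {
  tt <- toy_cache()
  tree <- cdt("SM", "ST", cache = tt$cache)
  gold_sm <- tt$tc$annotations[tt$tc$annotations$category == "SM",
                               c("id", "label")]
  pred <- classify(tree, tt$x, root_labels = gold_sm)
  # root category predictions equal the oracle exactly
  got_sm <- pred[pred$category == "SM", c("id", "label")]
  expect_equal(
    dplyr::arrange(got_sm, id, label),
    dplyr::arrange(gold_sm, id, label)
  )
  # downstream follows the oracle's branch
  expect_equal(pred$label[pred$id == "d1" & pred$category == "ST"], "Tone")
  expect_error(classify(tree, tt$x), "root_labels")
  bad <- tibble::tibble(id = "d1", label = "Tone") # ST label at SM root
  expect_error(classify(tree, tt$x, root_labels = bad), "Tone")
})

test_that("untrainable branches predict nothing downstream", {
  tc <- toy_corpus()
  # 'Word' never occurs in training, so the (ST=Word) child of any tree
  # has an empty restricted training set
  v <- build_vocabulary(tc$documents)
  x <- featurize(tc$documents, v)
  cache <- bdt_cache(tc$annotations, x, tc$schema)
  tree <- cdt("ST", "SM", cache = cache)
  oracle <- tibble::tibble(id = "d1", label = "Word")
  pred <- classify(tree, x["d1", , drop = FALSE], root_labels = oracle)
  expect_equal(pred$category, "ST") # only the oracle labels survive
  nodes <- tree_nodes(tree)
  word_node <- nodes[vapply(nodes$ancestors, identical, logical(1),
                            "ST:Word"), ]
  expect_false(word_node$trainable)
  expect_equal(word_node$n_train, 0)
})

test_that("back-off widens an untrainable node to its ancestor set", {
  tc <- toy_corpus()
  v <- build_vocabulary(tc$documents)
  x <- featurize(tc$documents, v)
  cache <- bdt_cache(tc$annotations, x, tc$schema)
  tree <- cdt("ST", "SM", backoff = TRUE, cache = cache)
  oracle <- tibble::tibble(id = "d1", label = "Word")
  pred <- classify(tree, x["d1", , drop = FALSE], root_labels = oracle)
  # with back-off the SM level falls back to the unrestricted classifier
  expect_true("SM" %in% pred$category)
})

test_that("trees and flat classification agree on dependency-free data", {
  schema <- onto_schema(
    c("A", "B"),
    list(A = c("a1", "a2"), B = c("b1", "b2", "b3"))
  )
  sim <- simulate_corpus(sim_config(
    schema = schema, n_docs = 250, dependency_strength = 0,
    mean_labels = c(A = 1.2, B = 1.3), seed = 21
  ))
  cvn <- cross_validate(sim$documents, sim$annotations, schema,
                        method = "NB", k = 5, seed = 2)
  cvb <- cross_validate(sim$documents, sim$annotations, schema,
                        method = "BDT", k = 5, seed = 2)
  nb <- summary(cvn)
  bdt_ <- summary(cvb)
  for (cc in schema$categories) {
    expect_lt(
      abs(nb$mean_f1[nb$category == cc] - bdt_$mean_f1[bdt_$category == cc]),
      0.1
    )
  }
})
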
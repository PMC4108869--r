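test_that("f_beta matches the closed form and its degenerate conventions", {
  expect_identical(f_beta(tp = 2, fp = 1, fn = 1, beta = 1), 2 / 3)
  expect_identical(f_beta(tp = 5, fp = 0, fn = 0), 1)
  expect_identical(f_beta(tp = 0, fp = 3, fn = 2), 0)
  expect_identical(f_beta(tp = 0, fp = 0, fn = 4), 0) # nothing predicted
  expect_identical(f_beta(tp = 0, fp = 4, fn = 0), 0) # nothing to find, fp
  expect_identical(f_beta(tp = 0, fp = 0, fn = 0), 1) # vacuous perfection
  # beta weighting: recall-heavy beta = 2
  p <- 2 / 3
  r <- 2 / 4
  expect_equal(
    f_beta(tp = 2, fp = 1, fn = 2, beta = 2),
    5 * p * r / (4 * p + r)
  )
})

test_that("f1_micro pools (document, label) pairs within a category", {
  gold <- tibble::tibble(
    id = c("d1", "d2"), category = "C", label = c("A", "B")
  )
  pred <- tibble::tibble(
    id = c("d1", "d2"), category = "C", label = c("A", "A")
  )
  expect_equal(f1_micro(gold, pred, "C"), 0.5) # tp 1, fp 1, fn 1
  empty <- pred[0, ]
  expect_equal(f1_micro(gold, empty, "C"), 0)
  expect_equal(f1_micro(gold, gold, "C"), 1)
  orphan <- tibble::tibble(id = "zz", category = "C", label = "A")
  expect_error(f1_micro(gold, orphan, "C"), "zz")
})

test_that("f1_micro equals f_beta applied to the pooled confusion counts", {
  set.seed(42)
  labs <- LETTERS[1:4]
  for (i in 1:10) {
    gold <- tibble::tibble(
      id = rep(paste0("d", 1:6), each = 2), category = "C",
      label = sample(labs, 12, replace = TRUE)
    ) |> dplyr::distinct()
    pred <- tibble::tibble(
      id = sample(paste0("d", 1:6), 8, replace = TRUE), category = "C",
      label = sample(labs, 8, replace = TRUE)
    ) |> dplyr::distinct()
    cc <- confusion_counts(gold, pred, "C")
    expect_identical(f1_micro(gold, pred, "C"),
                     f_beta(cc$tp, cc$fp, cc$fn, beta = 1))
    # tp + fn equals the number of gold pairs in the category
    expect_identical(cc$tp + cc$fn, nrow(gold))
  }
})

test_that("seeded folds partition the corpus and reproduce exactly", {
  ids <- paste0("d", 1:23)
  folds <- bayesannot:::make_folds(ids, k = 5, seed = 9)
  expect_length(folds, 5L)
  expect_setequal(unlist(folds), ids)
  expect_equal(sum(lengths(folds)), length(ids)) # each id exactly once
  expect_true(max(lengths(folds)) - min(lengths(folds)) <= 1L)
  expect_identical(folds, bayesannot:::make_folds(ids, k = 5, seed = 9))
  expect_error(bayesannot:::make_folds(ids, k = 24, seed = 1), "exceed")
})

small_sim <- function(n = 60, seed = 5) {
  simulate_corpus(sim_config(n_docs = n, seed = seed))
}

test_that("cross-validation is deterministic given the seed", {
  sim <- small_sim()
  cv1 <- cross_validate(sim$documents, sim$annotations, sim$schema,
                        method = "NB", k = 3, seed = 4)
  cv2 <- cross_validate(sim$documents, sim$annotations, sim$schema,
                        method = "NB", k = 3, seed = 4)
  expect_identical(tidy(cv1), tidy(cv2))
  expect_equal(nrow(tidy(cv1)), length(sim$schema$categories))
  expect_true(all(tidy(cv1)$f1 >= 0 & tidy(cv1)$f1 <= 1))
})

test_that("summary reports mean and n-1 standard deviation per category", {
  sim <- small_sim()
  # use a 3-category sub-schema so the full ordering sweep stays small
  cats <- c("SM", "RM", "RT")
  sub_schema <- onto_schema(cats, sim$schema$labels[cats],
                           sim$schema$restrictions[
                             sim$schema$restrictions$if_category %in% cats &
                               sim$schema$restrictions$then_category %in% cats,
                           ])
  sub_ann <- sim$annotations[sim$annotations$category %in% cats, ]
  cv <- cross_validate(sim$documents, sub_ann, sub_schema,
                       method = "BDT", k = 3, seed = 4)
  sc <- tidy(cv)
  expect_equal(length(unique(sc$tree)), factorial(3))
  sm <- summary(cv)
  manual <- sc[sc$category == "SM", ]$f1
  expect_equal(sm$mean_f1[sm$category == "SM"], mean(manual))
  expect_equal(sm$sd_f1[sm$category == "SM"], stats::sd(manual))
  expect_s3_class(autoplot(cv), "ggplot")
})

test_that("CDT scoring excludes each tree's oracle root category", {
  sim <- small_sim()
  cats <- c("SM", "RM", "RT")
  sub_schema <- onto_schema(cats, sim$schema$labels[cats], NULL)
  sub_ann <- sim$annotations[sim$annotations$category %in% cats, ]
  cv <- cross_validate(sim$documents, sub_ann, sub_schema,
                       method = "CDT", k = 3, seed = 4)
  sc <- tidy(cv)
  expect_true(all(sc$root != sc$category))
  # every root category appears, with (k_cat - 1)! orderings each
  expect_setequal(unique(sc$root), cats)
  expect_equal(length(unique(sc$tree)), 3 * factorial(2))
})

test_that("reports serialize scores with their summary statistics", {
  sim <- small_sim()
  cv <- cross_validate(sim$documents, sim$annotations, sim$schema,
                       method = "NB", k = 3, seed = 4)
  dir <- withr::local_tempdir()
  write_report(cv, dir)
  csv <- utils::read.csv(file.path(dir, "scores.csv"))
  expect_true(all(c("method", "category", "tree", "f1", "mean_f1", "sd_f1")
                  %in% names(csv)))
  expect_equal(nrow(csv), nrow(tidy(cv)))
  js <- jsonlite::read_json(file.path(dir, "summary.json"),
                            simplifyVector = TRUE)
  expect_equal(js$seed, 4)
  expect_equal(nrow(js$per_category), length(sim$schema$categories))
})
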
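#' F-beta score from pooled confusion counts
#'
#' precision = tp / (tp + fp), recall = tp / (tp + fn), and
#' F_beta = (1 + beta^2) * p * r / (beta^2 * p + r), with beta = 1 by
#' default. Degenerate pools: a zero denominator defines the corresponding
#' precision or recall as 0; the fully vacuous pool tp = fp = fn = 0 scores
#' 1 (nothing to find, nothing found).
#'
#' @param tp,fp,fn Non-negative pooled counts over (document, label) pairs
#'   (vectorized).
#' @param beta Positive weight on recall; default 1.
#' @return Numeric scores in \[0, 1\].
#' @export
f_beta <- function(tp, fp, fn, beta = 1) {
  stopifnot(beta > 0, all(tp >= 0), all(fp >= 0), all(fn >= 0))
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  num <- (1 + beta^2) * p * r
  den <- beta^2 * p + r
  out <- ifelse(den > 0, num / den, 0)
  ifelse(tp + fp + fn == 0, 1, out)
}

#' Pooled confusion counts for one category
#'
#' Counts true positives, false positives and false negatives over all
#' (document, label) pairs of one category, pooling across documents.
#' Documents with no predicted label in the category are not dropped: their
#' gold labels count as false negatives.
#'
#' @param gold,pred Annotation tibbles (`id`, `category`, `label`). The
#'   documents scored are those appearing in `gold`; an error is raised if
#'   `pred` mentions a document unknown to `gold`.
#' @param category Category to score.
#' @return A one-row tibble with columns `category`, `tp`, `fp`, `fn`.
#' @export
confusion_counts <- function(gold, pred, category) {
  orphan <- setdiff(unique(pred$id), unique(gold$id))
  if (length(orphan) > 0) {
    stop("prediction for document '", orphan[1],
      "' absent from the gold set",
      call. = FALSE
    )
  }
  g <- dplyr::distinct(gold[gold$category == category, c("id", "label")])
  p <- dplyr::distinct(pred[pred$category == category, c("id", "label")])
  tp <- nrow(dplyr::inner_join(g, p, by = c("id", "label")))
  tibble::tibble(
    category = category, tp = tp, fp = nrow(p) - tp, fn = nrow(g) - tp
  )
}

#' F1-micro for one category
#'
#' Pools tp/fp/fn over every (document, label) pair of the category, then
#' applies [f_beta()] with beta = 1: the harmonic mean of pooled precision
#' and recall.
#'
#' @inheritParams confusion_counts
#' @return A single score in \[0, 1\].
#' @export
f1_micro <- function(gold, pred, category) {
  cc <- confusion_counts(gold, pred, category)
  f_beta(cc$tp, cc$fp, cc$fn, beta = 1)
}

# seeded near-equal partition; one partition per run is shared by all
# methods so comparisons are paired
make_folds <- function(ids, k, seed) {
  n <- length(ids)
  if (k > n) stop("k = ", k, " folds exceed corpus size ", n, call. = FALSE)
  with_rng_seed(seed, {
    shuffled <- sample(ids)
  })
  fold <- rep(seq_len(k), length.out = n)
  split(shuffled, fold)
}

#' Cross-validated evaluation of the annotation methods
#'
#' Runs seeded k-fold cross-validation of one method over a corpus and
#' reports per-tree, per-category F1-micro scores pooled over the held-out
#' folds. Within each fold the vocabulary is rebuilt from the training
#' documents only, so no test token leaks into the feature space.
#'
#' Methods:
#' \describe{
#'   \item{NB}{one flat per-category naive Bayes classifier under binary
#'     relevance (one "tree" per run).}
#'   \item{BDT}{every category ordering — k_cat! trees (120 for five
#'     categories) — each scored separately, sharing node classifiers
#'     across trees through a per-fold cache.}
#'   \item{CDT}{for every root category, every ordering of the remaining
#'     categories, with gold labels supplied at the root; the root
#'     category's instances are excluded from that tree's scores.}
#' }
#'
#' @param documents Tibble (`id`, `text`).
#' @param annotations Gold-standard tibble (`id`, `category`, `label`).
#' @param schema An [onto_schema()].
#' @param method `"NB"`, `"BDT"` or `"CDT"`.
#' @param k Number of folds (default 10).
#' @param seed Integer seed driving the fold partition.
#' @param policy A [threshold_policy()]; default cutoff 0.1.
#' @param smoothing Pseudocount for [nb_fit()] (default 1).
#' @param min_train,backoff Node trainability controls, see [bdt()].
#' @param stopwords Stop-word list for [build_vocabulary()].
#' @param roots For CDT, the root categories to sweep (default all).
#' @return An object of class `onto_cv`; see [tidy.onto_cv()],
#'   [glance.onto_cv()], [summary.onto_cv()] and [autoplot.onto_cv()].
#' @export
cross_validate <- function(documents, annotations, schema,
                           method = c("NB", "BDT", "CDT"),
                           k = 10, seed = 1,
                           policy = threshold_policy(),
                           smoothing = 1, min_train = 1, backoff = FALSE,
                           stopwords = default_stopwords(),
                           roots = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(schema, "onto_schema"))
  documents <- tibble::as_tibble(documents)
  annotations <- tibble::as_tibble(annotations)
  validate_annotations(annotations, schema, documents, gold = TRUE)
  folds <- make_folds(documents$id, k, seed)
  cats <- schema$categories
  if (is.null(roots)) roots <- cats

  # predictions pooled out-of-fold, keyed by tree
  pooled <- list()
  for (fold in folds) {
    train_docs <- documents[!documents$id %in% fold, , drop = FALSE]
    test_docs <- documents[documents$id %in% fold, , drop = FALSE]
    train_ann <- annotations[annotations$id %in% train_docs$id, , drop = FALSE]
    test_ann <- annotations[annotations$id %in% test_docs$id, , drop = FALSE]
    vocab <- build_vocabulary(train_docs, stopwords)
    x_train <- featurize(train_docs, vocab)
    x_test <- featurize(test_docs, vocab)
    cache <- bdt_cache(train_ann, x_train, schema, smoothing, min_train)

    fold_preds <- switch(method,
      NB = {
        flat <- lapply(cats, function(cc) {
          node <- get_node(cache, cc, character(0))
          predict_labels(node$model, x_test, policy)[
            , c("id", "category", "label")
          ]
        })
        list(NB = dplyr::bind_rows(flat))
      },
      BDT = {
        ords <- category_orderings(cats)
        out <- lapply(ords, function(oo) {
          tree <- bdt(oo, policy = policy, backoff = backoff, cache = cache)
          classify(tree, x_test)
        })
        names(out) <- vapply(ords, paste, character(1), collapse = ">")
        out
      },
      CDT = {
        out <- list()
        for (root in roots) {
          oracle <- test_ann[test_ann$category == root, c("id", "label")]
          for (oo in category_orderings(setdiff(cats, root))) {
            tree <- cdt(root, oo,
              policy = policy, backoff = backoff, cache = cache
            )
            out[[paste(c(root, oo), collapse = ">")]] <-
              classify(tree, x_test, root_labels = oracle)
          }
        }
        out
      }
    )
    for (nm in names(fold_preds)) {
      pooled[[nm]] <- c(pooled[[nm]], list(fold_preds[[nm]]))
    }
  }

  scores <- purrr::map_dfr(names(pooled), function(nm) {
    pred <- dplyr::bind_rows(pooled[[nm]])
    root <- if (method == "CDT") strsplit(nm, ">", fixed = TRUE)[[1]][1] else NA_character_
    score_cats <- if (method == "CDT") setdiff(cats, root) else cats
    tibble::tibble(
      method = method,
      tree = nm,
      root = root,
      category = score_cats,
      f1 = vapply(score_cats, function(cc) {
        f1_micro(annotations, pred, cc)
      }, numeric(1))
    )
  })

  structure(
    list(
      scores = scores, method = method, k = k, seed = seed,
      alpha = policy$alpha, smoothing = smoothing, min_train = min_train,
      categories = cats, n_docs = nrow(documents)
    ),
    class = "onto_cv"
  )
}

#' @export
print.onto_cv <- function(x, ...) {
  cat("<onto_cv> method ", x$method, ", ", x$n_docs, " documents, ",
    x$k, "-fold CV (seed ", x$seed, "), ",
    length(unique(x$scores$tree)), " tree(s)\n",
    sep = ""
  )
  print(summary(x))
  invisible(x)
}

#' Per-category score summary
#'
#' Mean and standard deviation (n - 1 denominator) of the per-tree F1-micro
#' scores in each category. For a Constrained Decision Tree run, a
#' category's summary covers only the trees in which it was not the
#' oracle-supplied root.
#'
#' @param object An `onto_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A tibble with columns `method`, `category`, `mean_f1`, `sd_f1`,
#'   `n_trees`.
#' @export
summary.onto_cv <- function(object, ...) {
  object$scores |>
    dplyr::group_by(.data$method, .data$category) |>
    dplyr::summarise(
      mean_f1 = mean(.data$f1),
      sd_f1 = if (dplyr::n() > 1) stats::sd(.data$f1) else NA_real_,
      n_trees = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$category, object$categories))
}

#' @rdname summary.onto_cv
#' @param x An `onto_cv`.
#' @export
tidy.onto_cv <- function(x, ...) {
  x$scores
}

#' @rdname summary.onto_cv
#' @export
glance.onto_cv <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    mean_f1 = mean(x$scores$f1),
    n_trees = length(unique(x$scores$tree)),
    n_docs = x$n_docs,
    k = x$k,
    seed = x$seed,
    alpha = x$alpha,
    smoothing = x$smoothing
  )
}

#' Bar chart of per-category F1-micro
#'
#' One bar per category (mean across trees) with error bars at twice the
#' standard deviation of the per-tree scores. Pass several `onto_cv` runs to
#' compare methods side by side.
#'
#' @param object An `onto_cv` from [cross_validate()].
#' @param ... Further `onto_cv` objects to overlay.
#' @return A ggplot object.
#' @export
autoplot.onto_cv <- function(object, ...) {
  extra <- Filter(function(o) inherits(o, "onto_cv"), list(...))
  smry <- dplyr::bind_rows(lapply(c(list(object), extra), summary))
  smry$category <- factor(smry$category, levels = object$categories)
  smry$lo <- pmax(0, smry$mean_f1 - 2 * dplyr::coalesce(smry$sd_f1, 0))
  smry$hi <- pmin(1, smry$mean_f1 + 2 * dplyr::coalesce(smry$sd_f1, 0))
  ggplot2::ggplot(smry, ggplot2::aes(
    x = .data$category, y = .data$mean_f1, fill = .data$method
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "F1-micro (mean ± 2 SD across trees)",
      fill = "method"
    ) +
    ggplot2::theme_minimal()
}

#' Write an evaluation report to disk
#'
#' Emits `scores.csv` (method, category, tree ordering, root, fold-pooled
#' F1, with the per-category mean and SD joined on) and `summary.json`.
#'
#' @param cv An `onto_cv`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_report <- function(cv, dir) {
  stopifnot(inherits(cv, "onto_cv"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  smry <- summary(cv)
  rows <- dplyr::left_join(cv$scores, smry, by = c("method", "category"))
  utils::write.csv(rows, file.path(dir, "scores.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(
      method = cv$method, k = cv$k, seed = cv$seed, alpha = cv$alpha,
      smoothing = cv$smoothing, n_docs = cv$n_docs,
      per_category = smry
    ),
    file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
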
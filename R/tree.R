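#' Enumerate category orderings
#'
#' A Bayesian Decision Tree assigns one ontology category per tree level, so
#' a k-category schema admits exactly k! distinct trees. The five-category
#' stimulus/response/instruction schema yields 120.
#'
#' @param categories Character vector of category names, or an
#'   [onto_schema()].
#' @return A list of character vectors, each a permutation of `categories`.
#' @export
category_orderings <- function(categories) {
  if (inherits(categories, "onto_schema")) categories <- categories$categories
  perms(categories)
}

perms <- function(v) {
  if (length(v) <= 1L) {
    return(list(v))
  }
  out <- lapply(seq_along(v), function(i) {
    lapply(perms(v[-i]), function(p) c(v[i], p))
  })
  unlist(out, recursive = FALSE)
}

label_key <- function(category, label) paste(category, label, sep = "\a")

#' Shared classifier cache for tree construction
#'
#' Node classifiers in a Bayesian Decision Tree depend only on the predicted
#' category and the ancestor label set (which determines the restricted
#' training set), not on the ordering that reached them. A cache built once
#' per training corpus is therefore shared across all trees of an ordering
#' sweep: identical nodes are fitted once.
#'
#' @param annotations Gold-standard tibble (`id`, `category`, `label`) for
#'   the training documents.
#' @param features Logical document-by-feature training matrix.
#' @param schema An [onto_schema()].
#' @param smoothing Pseudocount passed to [nb_fit()].
#' @param min_train Minimum restricted-training-set size below which a node
#'   is marked untrainable (default 1: any non-empty set trains, relying on
#'   smoothing).
#' @return An environment of class `bdt_cache`.
#' @export
bdt_cache <- function(annotations, features, schema, smoothing = 1,
                      min_train = 1) {
  stopifnot(inherits(schema, "onto_schema"))
  annotations <- tibble::as_tibble(annotations)
  validate_annotations(annotations, schema)
  ids <- rownames(features)
  if (!all(unique(annotations$id) %in% ids)) {
    stop("gold annotations must cover only documents in the feature matrix",
      call. = FALSE
    )
  }
  all_keys <- unlist(lapply(schema$categories, function(cc) {
    label_key(cc, schema$labels[[cc]])
  }))
  gold <- matrix(FALSE, nrow = length(ids), ncol = length(all_keys),
                 dimnames = list(ids, all_keys))
  gold[cbind(
    match(annotations$id, ids),
    match(label_key(annotations$category, annotations$label), all_keys)
  )] <- TRUE
  cache <- new.env(parent = emptyenv())
  cache$features <- features
  cache$annotations <- annotations
  cache$schema <- schema
  cache$gold <- gold
  cache$smoothing <- smoothing
  cache$min_train <- max(1L, as.integer(min_train))
  cache$nodes <- new.env(parent = emptyenv())
  cache$models <- new.env(parent = emptyenv()) # keyed by (category, S_t)
  cache$preds <- new.env(parent = emptyenv())
  class(cache) <- "bdt_cache"
  cache
}

# training-set restriction of Definition-style ancestor conditioning:
# S_t = documents whose gold labels contain every ancestor label
restricted_ids <- function(cache, ancestor_keys) {
  if (length(ancestor_keys) == 0L) {
    return(rownames(cache$features))
  }
  g <- cache$gold[, ancestor_keys, drop = FALSE]
  rownames(cache$features)[rowSums(g) == length(ancestor_keys)]
}

get_node <- function(cache, category, ancestor_keys) {
  nk <- paste(category, paste(ancestor_keys, collapse = "\a"), sep = "\r")
  if (!is.null(cache$nodes[[nk]])) {
    return(cache$nodes[[nk]])
  }
  ids <- restricted_ids(cache, ancestor_keys)
  # distinct ancestor sets often induce the same restricted training set
  # (entailed labels add no restriction), and then the same classifier
  mk <- paste(category,
    paste(match(ids, rownames(cache$features)), collapse = ","),
    sep = "|"
  )
  node <- list(
    category = category,
    ancestors = ancestor_keys,
    training_ids = ids,
    n_train = length(ids),
    model_key = mk,
    model = NULL
  )
  if (length(ids) >= cache$min_train) {
    model <- cache$models[[mk]]
    if (is.null(model)) {
      ann <- cache$annotations[cache$annotations$id %in% ids, , drop = FALSE]
      model <- nb_fit(
        ann, cache$features[ids, , drop = FALSE],
        category, cache$schema, cache$smoothing
      )
      cache$models[[mk]] <- model
    }
    node$model <- model
  }
  cache$nodes[[nk]] <- node
  node
}

# back-off (optional): drop the most recently added ancestor restriction
# until the node trains
node_model <- function(cache, category, path_keys, backoff) {
  node <- get_node(cache, category, path_keys)
  if (!is.null(node$model) || !backoff) {
    return(node)
  }
  keys <- path_keys
  while (is.null(node$model) && length(keys) > 0L) {
    keys <- keys[-length(keys)]
    node <- get_node(cache, category, keys)
  }
  node
}

#' Materialized tree nodes
#'
#' Every node fitted so far in a cache (or a tree's cache): its category,
#' ancestor label set, restricted-training-set size and trainability.
#'
#' @param x A `bdt_cache`, or a tree built by [bdt()] / [cdt()].
#' @return A tibble with columns `category`, `ancestors` (list column of
#'   `"category:label"` strings), `n_train`, `trainable`.
#' @export
tree_nodes <- function(x) {
  cache <- if (inherits(x, "onto_bdt")) x$cache else x
  stopifnot(inherits(cache, "bdt_cache"))
  nodes <- unname(as.list(cache$nodes))
  tibble::tibble(
    category = vapply(nodes, function(n) n$category, character(1)),
    ancestors = lapply(nodes, function(n) {
      sub("\a", ":", n$ancestors, fixed = TRUE)
    }),
    n_train = vapply(nodes, function(n) n$n_train, numeric(1)),
    trainable = vapply(nodes, function(n) !is.null(n$model), logical(1)),
    training_ids = lapply(nodes, function(n) n$training_ids)
  )
}

#' Build a Bayesian Decision Tree
#'
#' A Bayesian Decision Tree for a category ordering predicts the first
#' category at the root with a naive Bayes classifier trained on the full
#' training set, and each deeper node's category with a classifier trained
#' only on documents whose gold labels include all ancestor labels. This
#' restriction lets each node exploit cross-category label dependencies
#' present in the expert annotations. Nodes are constructed lazily: beyond
#' the eagerly fitted root, a node is materialized the first time traversal
#' reaches it. Nodes whose restricted training set has fewer than
#' `min_train` documents are marked untrainable and contribute neither
#' labels nor children.
#'
#' @param ordering Character vector: a permutation of (a subset of) schema
#'   categories, root category first.
#' @param annotations,features,schema,smoothing,min_train Training corpus as
#'   in [bdt_cache()]; ignored when `cache` is supplied.
#' @param policy A [threshold_policy()] applied at every node.
#' @param backoff If `TRUE`, an untrainable node falls back to the classifier
#'   with its most recent ancestor restriction dropped (default `FALSE`: the
#'   restriction is never silently widened).
#' @param cache Optional shared [bdt_cache()] so an ordering sweep reuses
#'   node classifiers across trees.
#' @return An object of class `onto_bdt`.
#' @export
bdt <- function(ordering, annotations = NULL, features = NULL, schema = NULL,
                policy = threshold_policy(), smoothing = 1, min_train = 1,
                backoff = FALSE, cache = NULL) {
  if (length(ordering) == 0L) {
    stop("ordering must contain at least one category", call. = FALSE)
  }
  if (is.null(cache)) {
    cache <- bdt_cache(annotations, features, schema, smoothing, min_train)
  }
  schema <- cache$schema
  if (!all(ordering %in% schema$categories) || anyDuplicated(ordering)) {
    stop("ordering must be distinct schema categories", call. = FALSE)
  }
  get_node(cache, ordering[1], character(0)) # root: full training set
  structure(
    list(
      ordering = as.character(ordering), cache = cache, policy = policy,
      backoff = isTRUE(backoff), constrained = FALSE
    ),
    class = "onto_bdt"
  )
}

#' Build a Constrained Decision Tree
#'
#' The human-in-the-loop variant of [bdt()]: the root category's labels are
#' supplied externally (by an expert, or by the gold standard as an oracle)
#' instead of being predicted, and traversal proceeds into the corresponding
#' children. When scoring a Constrained Decision Tree, the root category's
#' instances are excluded, since they were assigned by the expert.
#'
#' @param root_category The category whose labels the expert supplies.
#' @param ordering_rest Permutation of the remaining categories.
#' @inheritParams bdt
#' @return An object of class `onto_cdt` (also an `onto_bdt`).
#' @export
cdt <- function(root_category, ordering_rest, annotations = NULL,
                features = NULL, schema = NULL, policy = threshold_policy(),
                smoothing = 1, min_train = 1, backoff = FALSE, cache = NULL) {
  if (is.null(cache)) {
    cache <- bdt_cache(annotations, features, schema, smoothing, min_train)
  }
  schema <- cache$schema
  if (!root_category %in% schema$categories) {
    stop("unknown root category '", root_category, "'", call. = FALSE)
  }
  ordering <- c(root_category, ordering_rest)
  if (!all(ordering %in% schema$categories) || anyDuplicated(ordering)) {
    stop("ordering must be distinct schema categories", call. = FALSE)
  }
  structure(
    list(
      ordering = as.character(ordering), cache = cache, policy = policy,
      backoff = isTRUE(backoff), constrained = TRUE
    ),
    class = c("onto_cdt", "onto_bdt")
  )
}

#' @export
print.onto_bdt <- function(x, ...) {
  cat("<", if (x$constrained) "onto_cdt" else "onto_bdt", "> ordering: ",
    paste(x$ordering, collapse = " > "),
    if (x$constrained) " (root supplied by expert)" else "",
    "; alpha = ", x$policy$alpha, "\n",
    sep = ""
  )
  invisible(x)
}

#' Classify documents with a decision tree
#'
#' Breadth-first traversal: starting at the root, each node's classifier
#' proposes the labels above the threshold, the output accumulates them, and
#' for every proposed label the corresponding child (next category in the
#' ordering, restricted by the enlarged ancestor label set) is enqueued.
#' A document following several labels at one level explores several
#' branches, and the downstream predictions are unioned per category.
#' Untrainable nodes contribute no labels and no children, so categories
#' below a dead branch receive empty predictions for the documents on it.
#'
#' @param tree An [bdt()] or [cdt()] tree.
#' @param features Logical document-by-feature matrix over the tree's
#'   vocabulary (rows named by document id).
#' @param root_labels For a Constrained Decision Tree only: a tibble with
#'   columns `id`, `label` giving the expert-supplied root-category labels.
#' @return A tibble with columns `id`, `category`, `label` (no duplicates).
#' @export
classify <- function(tree, features, root_labels = NULL) {
  UseMethod("classify")
}

#' @export
classify.onto_bdt <- function(tree, features, root_labels = NULL) {
  if (!is.null(root_labels) && !tree$constrained) {
    stop("root_labels is only meaningful for a Constrained Decision Tree",
      call. = FALSE
    )
  }
  check_features(tree, features)
  frontier <- list(list(keys = character(0), docs = rownames(features)))
  traverse(tree, features, frontier, depth_from = 1L)
}

#' @export
classify.onto_cdt <- function(tree, features, root_labels = NULL) {
  if (is.null(root_labels)) {
    stop("a Constrained Decision Tree needs expert-supplied `root_labels`",
      call. = FALSE
    )
  }
  check_features(tree, features)
  root_cat <- tree$ordering[1]
  root_labels <- tibble::as_tibble(root_labels)[, c("id", "label")]
  bad <- setdiff(unique(root_labels$label), tree$cache$schema$labels[[root_cat]])
  if (length(bad) > 0) {
    stop("supplied root label '", bad[1], "' is not in category '",
      root_cat, "'",
      call. = FALSE
    )
  }
  root_labels <- root_labels[root_labels$id %in% rownames(features), ,
                             drop = FALSE]
  oracle <- tibble::tibble(
    id = root_labels$id, category = root_cat, label = root_labels$label
  )
  frontier <- list()
  for (l in unique(root_labels$label)) {
    frontier[[length(frontier) + 1L]] <- list(
      keys = label_key(root_cat, l),
      docs = unique(root_labels$id[root_labels$label == l])
    )
  }
  below <- traverse(tree, features, frontier, depth_from = 2L)
  dplyr::distinct(dplyr::bind_rows(oracle, below))
}

check_features <- function(tree, features) {
  if (!identical(colnames(features), colnames(tree$cache$features))) {
    stop("feature matrix does not match the tree's vocabulary", call. = FALSE)
  }
  invisible(TRUE)
}

# memoized per-(node, document) label prediction: a node's output for a
# document depends only on its classifier and the threshold policy, never on
# which ordering reached it, so the ordering sweep computes each pair once
node_predict <- function(cache, node, docs, x, policy) {
  pk <- paste(node$model_key, policy$alpha, policy$fallback_argmax,
              sep = "\r")
  env <- cache$preds[[pk]]
  if (is.null(env)) {
    env <- new.env(parent = emptyenv())
    cache$preds[[pk]] <- env
  }
  miss <- docs[!vapply(docs, exists, logical(1),
                       envir = env, inherits = FALSE)]
  if (length(miss) > 0L) {
    p <- posterior_core(node$model, x[miss, , drop = FALSE])
    sel <- p > policy$alpha
    if (policy$fallback_argmax) {
      none <- rowSums(sel) == 0L
      if (any(none)) {
        top <- max.col(p[none, , drop = FALSE], ties.method = "first")
        sel[cbind(which(none), top)] <- TRUE
      }
    }
    labs <- node$model$labels
    for (i in seq_along(miss)) {
      env[[miss[i]]] <- labs[sel[i, ]]
    }
  }
  mget(docs, envir = env)
}

# level-wise batch form of the breadth-first traversal: all documents at the
# same node are classified together; equivalent to the per-document queue
# since node outputs are unioned per category
traverse <- function(tree, features, frontier, depth_from) {
  ordering <- tree$ordering
  out_id <- list()
  out_cat <- character(0)
  out_lab <- list()
  depths <- seq_len(length(ordering))
  depths <- depths[depths >= depth_from]
  for (depth in depths) {
    cat_d <- ordering[depth]
    nxt <- list()
    for (br in frontier) {
      node <- node_model(tree$cache, cat_d, br$keys, tree$backoff)
      if (is.null(node$model)) next
      pl <- node_predict(tree$cache, node, br$docs, features, tree$policy)
      nl <- lengths(pl)
      if (all(nl == 0L)) next
      ids <- rep(br$docs, nl)
      labs <- unlist(pl, use.names = FALSE)
      out_id[[length(out_id) + 1L]] <- ids
      out_cat <- c(out_cat, cat_d)
      out_lab[[length(out_lab) + 1L]] <- labs
      if (depth < length(ordering)) {
        by_lab <- split(ids, labs)
        for (l in names(by_lab)) {
          ck <- c(br$keys, label_key(cat_d, l))
          kk <- paste(ck, collapse = "\r")
          if (is.null(nxt[[kk]])) {
            nxt[[kk]] <- list(keys = ck, docs = by_lab[[l]])
          } else {
            nxt[[kk]]$docs <- unique(c(nxt[[kk]]$docs, by_lab[[l]]))
          }
        }
      }
    }
    frontier <- unname(nxt)
  }
  if (length(out_id) == 0L) {
    return(tibble::tibble(
      id = character(), category = character(), label = character()
    ))
  }
  res <- tibble::tibble(
    id = unlist(out_id, use.names = FALSE),
    category = rep(out_cat, vapply(out_id, length, integer(1))),
    label = unlist(out_lab, use.names = FALSE)
  )
  res[!duplicated(paste(res$id, res$category, res$label, sep = "\r")), ]
}
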
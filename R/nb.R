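#' Threshold policy for multi-label prediction
#'
#' Under binary relevance, every label whose posterior exceeds the cutoff
#' `alpha` is accepted (strictly greater than, so a posterior exactly equal
#' to `alpha` is excluded). With `fallback_argmax = TRUE`, a document whose
#' posteriors all fall at or below `alpha` still receives the single
#' highest-posterior label; by default it receives no label.
#'
#' @param alpha Probability cutoff in \[0, 1\]; default 0.1.
#' @param fallback_argmax Logical; default `FALSE`.
#' @return A `threshold_policy` object.
#' @export
threshold_policy <- function(alpha = 0.1, fallback_argmax = FALSE) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  structure(
    list(alpha = alpha, fallback_argmax = isTRUE(fallback_argmax)),
    class = "threshold_policy"
  )
}

#' Fit a per-category multi-label naive Bayes model
#'
#' Estimates, for one ontology category, the label priors P(l), the
#' per-feature conditionals P(b_i = TRUE | l) and P(b_i = TRUE | not l), and
#' the feature marginals P(b_i = TRUE), from an annotated training corpus of
#' Boolean feature vectors. All estimates are relative frequencies with an
#' additive (Laplace) pseudocount: with smoothing s, a label seen in n_l of N
#' documents has prior (n_l + s) / (N + 2s), and a feature TRUE in c of the
#' n_l label-positive documents has conditional (c + s) / (n_l + 2s). Labels
#' of the category absent from the training set still get (pure-smoothing)
#' estimates. With the default s = 1 no estimate is ever 0 or 1, so the
#' log-space posterior never meets -Inf.
#'
#' @param annotations Tibble with columns `id`, `category`, `label`; rows of
#'   other categories are ignored. Every id must be a row of `features`.
#' @param features Logical document-by-feature matrix from [featurize()],
#'   rows named by document id. All rows are used as the training set.
#' @param category The category to model.
#' @param schema An [onto_schema()] providing the category's label inventory.
#' @param smoothing Additive pseudocount, default 1 (Laplace).
#' @return An object of class `onto_nb`.
#' @export
nb_fit <- function(annotations, features, category, schema, smoothing = 1) {
  stopifnot(inherits(schema, "onto_schema"))
  if (!category %in% schema$categories) {
    stop("unknown category '", category, "'", call. = FALSE)
  }
  n <- nrow(features)
  if (is.null(n) || n == 0L) {
    stop(untrainable_error("empty training set for category '", category, "'"))
  }
  ann <- annotations[annotations$category == category, , drop = FALSE]
  bad <- setdiff(unique(ann$label), schema$labels[[category]])
  if (length(bad) > 0) {
    stop("training label '", bad[1], "' not in category '", category, "'",
      call. = FALSE
    )
  }
  if (!all(ann$id %in% rownames(features))) {
    stop("annotation id missing from feature matrix", call. = FALSE)
  }
  labels <- schema$labels[[category]]
  s <- smoothing
  # label-by-document membership, then one cross-product for all TRUE counts
  memb <- matrix(FALSE, nrow = length(labels), ncol = n,
                 dimnames = list(labels, rownames(features)))
  if (nrow(ann) > 0) {
    memb[cbind(match(ann$label, labels), match(ann$id, rownames(features)))] <- TRUE
  }
  n_l <- rowSums(memb)
  feat_true <- colSums(features)
  true_with <- memb %*% features             # labels x features
  true_without <- rep(feat_true, each = length(labels)) - true_with
  dim(true_without) <- dim(true_with)
  dimnames(true_without) <- dimnames(true_with)

  model <- structure(
    list(
      category = category,
      labels = labels,
      features = colnames(features),
      label_prior = stats::setNames((n_l + s) / (n + 2 * s), labels),
      p_true_given_label = (true_with + s) / (n_l + 2 * s),
      p_true_given_notlabel = (true_without + s) / ((n - n_l) + 2 * s),
      p_true_marginal = stats::setNames((feat_true + s) / (n + 2 * s),
                                        colnames(features)),
      training_size = n,
      smoothing = s
    ),
    class = "onto_nb"
  )
  finalize_model(model)
}

finalize_model <- function(model) {
  # with a positive pseudocount every relative frequency is strictly inside
  # (0, 1) by construction; only unsmoothed models need the full scan
  model$smoothed <- model$smoothing > 0 ||
    (!anyNA(model$label_prior) &&
       all(model$label_prior > 0) && all(model$label_prior < 1) &&
       all(model$p_true_given_label > 0) &&
       all(model$p_true_given_label < 1) &&
       all(model$p_true_given_notlabel > 0) &&
       all(model$p_true_given_notlabel < 1))
  if (model$smoothed) {
    lq1 <- log1p(-model$p_true_given_label)
    lq0 <- log1p(-model$p_true_given_notlabel)
    model$.loglik <- list(
      w1 = log(model$p_true_given_label) - lq1,
      w0 = log(model$p_true_given_notlabel) - lq0,
      b1 = rowSums(lq1) + log(model$label_prior),
      b0 = rowSums(lq0) + log1p(-model$label_prior)
    )
  }
  model
}

untrainable_error <- function(...) {
  structure(
    class = c("bayesannot_untrainable", "error", "condition"),
    list(message = paste0(...), call = NULL)
  )
}

#' @export
print.onto_nb <- function(x, ...) {
  cat("<onto_nb> category '", x$category, "': ", length(x$labels),
    " labels, ", length(x$features), " features, trained on ",
    x$training_size, " documents (smoothing ", x$smoothing, ")\n",
    sep = ""
  )
  invisible(x)
}

check_model_smoothed <- function(model) {
  smoothed <- model$smoothed
  if (is.null(smoothed)) {
    p <- c(
      model$label_prior, model$p_true_given_label,
      model$p_true_given_notlabel
    )
    smoothed <- all(p > 0) && all(p < 1)
  }
  if (!smoothed) {
    stop("model parameters must lie strictly in (0, 1); refit with ",
      "smoothing > 0",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

# normalized two-class posterior, matrix in / matrix out, no validation;
# log-likelihood contrasts are cached on the model the first time
posterior_core <- function(model, x) {
  ll <- model$.loglik
  if (is.null(ll)) {
    lq1 <- log1p(-model$p_true_given_label)
    lq0 <- log1p(-model$p_true_given_notlabel)
    ll <- list(
      w1 = log(model$p_true_given_label) - lq1,
      w0 = log(model$p_true_given_notlabel) - lq0,
      b1 = rowSums(lq1) + log(model$label_prior),
      b0 = rowSums(lq0) + log1p(-model$label_prior)
    )
  }
  s1 <- tcrossprod(x, ll$w1) + rep(ll$b1, each = nrow(x))
  s0 <- tcrossprod(x, ll$w0) + rep(ll$b0, each = nrow(x))
  out <- 1 / (1 + exp(s0 - s1))
  colnames(out) <- model$labels
  rownames(out) <- rownames(x)
  out
}

as_feature_matrix <- function(v, model) {
  if (is.null(dim(v))) {
    if (length(v) != length(model$features)) {
      stop("feature vector length ", length(v), " does not match model's ",
        length(model$features), " features",
        call. = FALSE
      )
    }
    v <- matrix(v, nrow = 1, dimnames = list("doc", model$features))
  }
  if (ncol(v) != length(model$features)) {
    stop("feature matrix has ", ncol(v), " columns; model expects ",
      length(model$features),
      call. = FALSE
    )
  }
  storage.mode(v) <- "double"
  v
}

#' Per-label posterior probabilities
#'
#' For each label l of the model's category, computes the normalized
#' two-class posterior P(l | v) = s1 / (s1 + s0), where
#' s1 = P(l) * prod_i P(b_i | l) and s0 = (1 - P(l)) * prod_i P(b_i | not l),
#' under the naive assumption that feature bits are independent given the
#' label. Products are accumulated as log-sums; exponentiation happens only
#' in the final normalization, so long vocabularies do not underflow. With
#' `score = "raw"` the unnormalized score P(l) * prod_i P(b_i | l) / P(b_i)
#' is returned instead (it can exceed 1 and is kept for comparison only).
#'
#' @param model An [nb_fit()] model.
#' @param v A logical feature vector of the model's dimension, or a
#'   document-by-feature matrix of such vectors.
#' @param label Optionally restrict the result to one label.
#' @param score `"normalized"` (default) or `"raw"`.
#' @return For a single vector, a named numeric vector over labels (or a
#'   scalar when `label` is given); for a matrix, a document-by-label matrix.
#' @export
posterior <- function(model, v, label = NULL,
                      score = c("normalized", "raw")) {
  stopifnot(inherits(model, "onto_nb"))
  score <- match.arg(score)
  check_model_smoothed(model)
  single <- is.null(dim(v))
  x <- as_feature_matrix(v, model)
  if (score == "normalized") {
    out <- posterior_core(model, x)
  } else {
    lp1 <- log(model$p_true_given_label)
    lq1 <- log1p(-model$p_true_given_label)
    lm1 <- log(model$p_true_marginal)
    lm0 <- log1p(-model$p_true_marginal)
    ll <- sweep(lp1 - lq1, 2, lm1 - lm0, "-")
    base <- rowSums(lq1) - rep(sum(lm0), length(model$labels))
    out <- exp(x %*% t(ll) +
      rep(base, each = nrow(x)) +
      rep(log(model$label_prior), each = nrow(x)))
  }
  colnames(out) <- model$labels
  rownames(out) <- rownames(x)
  if (!is.null(label)) {
    if (!label %in% model$labels) {
      stop("unknown label '", label, "'", call. = FALSE)
    }
    out <- out[, label]
    if (!single) names(out) <- rownames(x)
  } else if (single) {
    out <- out[1L, ]
  }
  out
}

#' Predict a label set under a threshold policy
#'
#' Applies [posterior()] and returns every label strictly above the policy's
#' cutoff. Deterministic given model and input: labels are ordered by
#' descending posterior with lexicographic tie-break.
#'
#' @inheritParams posterior
#' @param policy A [threshold_policy()].
#' @return For a single vector, a character vector of labels; for a matrix,
#'   a tibble with columns `id`, `category`, `label`, `posterior`.
#' @export
predict_labels <- function(model, v, policy = threshold_policy()) {
  stopifnot(inherits(policy, "threshold_policy"))
  single <- is.null(dim(v))
  p <- posterior(model, v)
  if (single) p <- matrix(p, nrow = 1, dimnames = list("doc", model$labels))
  sel <- p > policy$alpha
  if (policy$fallback_argmax) {
    none <- rowSums(sel) == 0L
    if (any(none)) {
      top <- max.col(p[none, , drop = FALSE], ties.method = "first")
      sel[cbind(which(none), top)] <- TRUE
    }
  }
  idx <- which(sel, arr.ind = TRUE)
  out <- tibble::tibble(
    id = rownames(p)[idx[, 1]],
    category = model$category,
    label = model$labels[idx[, 2]],
    posterior = p[idx]
  )
  out <- out[order(match(out$id, rownames(p)), -out$posterior, out$label), ]
  if (single) {
    return(out$label)
  }
  out
}

#' Serialize a naive Bayes model to JSON
#'
#' Writes priors, conditionals and marginals at full decimal precision;
#' `nb_read()` restores a model that round-trips exactly through the stored
#' decimal representation.
#'
#' @param model An [nb_fit()] model.
#' @param path File path.
#' @export
nb_write <- function(model, path) {
  stopifnot(inherits(model, "onto_nb"))
  obj <- list(
    category = model$category,
    labels = model$labels,
    features = model$features,
    label_prior = unname(model$label_prior),
    p_true_given_label = model$p_true_given_label,
    p_true_given_notlabel = model$p_true_given_notlabel,
    p_true_marginal = unname(model$p_true_marginal),
    training_size = model$training_size,
    smoothing = model$smoothing
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname nb_write
#' @export
nb_read <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- as.character(raw$labels)
  features <- as.character(raw$features)
  shape <- function(m) {
    m <- matrix(as.numeric(m), nrow = length(labels),
                dimnames = list(labels, features))
    m
  }
  model <- structure(
    list(
      category = as.character(raw$category),
      labels = labels,
      features = features,
      label_prior = stats::setNames(as.numeric(raw$label_prior), labels),
      p_true_given_label = shape(raw$p_true_given_label),
      p_true_given_notlabel = shape(raw$p_true_given_notlabel),
      p_true_marginal = stats::setNames(as.numeric(raw$p_true_marginal),
                                        features),
      training_size = as.integer(raw$training_size),
      smoothing = as.numeric(raw$smoothing)
    ),
    class = "onto_nb"
  )
  finalize_model(model)
}

#' @export
tidy.onto_nb <- function(x, ...) {
  prior <- tibble::tibble(
    category = x$category, label = x$labels,
    term = "prior", feature = NA_character_,
    estimate = unname(x$label_prior)
  )
  cond <- tibble::tibble(
    category = x$category,
    label = rep(x$labels, times = length(x$features)),
    term = "p_true_given_label",
    feature = rep(x$features, each = length(x$labels)),
    estimate = as.vector(x$p_true_given_label)
  )
  dplyr::bind_rows(prior, cond)
}

#' @export
glance.onto_nb <- function(x, ...) {
  tibble::tibble(
    category = x$category,
    n_labels = length(x$labels),
    n_features = length(x$features),
    n_train = x$training_size,
    smoothing = x$smoothing
  )
}
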
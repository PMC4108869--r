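# small fixed fixtures and independent oracles shared across test files

toy_schema <- function() {
  onto_schema(
    categories = c("SM", "ST"),
    labels = list(
      SM = c("Auditory", "Visual"),
      ST = c("Tone", "Picture", "Word")
    ),
    restrictions = data.frame(
      if_label = "Tone", if_category = "ST",
      then_label = "Auditory", then_category = "SM"
    )
  )
}

# six hand-written documents with perfectly separable word signal
toy_corpus <- function() {
  documents <- tibble::tibble(
    id = paste0("d", 1:6),
    text = c(
      "tone beep chord sound",
      "tone beep sound noise",
      "beep chord tone hum",
      "tone hum sound beep",
      "flash dot picture image",
      "picture image flash grid"
    )
  )
  annotations <- tibble::tibble(
    id = rep(paste0("d", 1:6), each = 2),
    category = rep(c("SM", "ST"), times = 6),
    label = c(
      "Auditory", "Tone", "Auditory", "Tone", "Auditory", "Tone",
      "Auditory", "Tone", "Visual", "Picture", "Visual", "Picture"
    )
  )
  list(documents = documents, annotations = annotations,
       schema = toy_schema())
}

# brute-force Bayes oracle: enumerate the full joint over all 2^m feature
# vectors for the label / not-label classes with plain products (no logs),
# then read the posterior of v off the table
oracle_posterior <- function(model, v, label) {
  m <- length(model$features)
  stopifnot(m <= 12)
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  p1 <- model$p_true_given_label[label, ]
  p0 <- model$p_true_given_notlabel[label, ]
  prior <- model$label_prior[[label]]
  joint1 <- apply(grid, 1, function(b) prior * prod(ifelse(b, p1, 1 - p1)))
  joint0 <- apply(grid, 1, function(b) {
    (1 - prior) * prod(ifelse(b, p0, 1 - p0))
  })
  row <- which(apply(grid, 1, function(b) all(b == v)))
  joint1[row] / (joint1[row] + joint0[row])
}

# a randomly parameterized smoothed model, built through the public fit
# interface from a random annotated corpus
random_model <- function(n_features, n_labels = 3, n_docs = 12, seed = 1) {
  set.seed(seed)
  labs <- LETTERS[seq_len(n_labels)]
  schema <- onto_schema("C", list(C = labs))
  x <- matrix(stats::runif(n_docs * n_features) < 0.5, n_docs, n_features,
    dimnames = list(
      paste0("d", seq_len(n_docs)),
      paste0("f", seq_len(n_features))
    )
  )
  ann <- tibble::tibble(
    id = sample(rownames(x), n_docs * 2, replace = TRUE),
    category = "C",
    label = sample(labs, n_docs * 2, replace = TRUE)
  )
  ann <- dplyr::distinct(ann)
  nb_fit(ann, x, "C", schema, smoothing = stats::runif(1, 0.5, 2))
}

# a model whose only information is the label prior (no features), so the
# posterior equals the prior exactly
prior_only_model <- function(priors) {
  schema <- onto_schema("C", list(C = names(priors)))
  x <- matrix(logical(0), nrow = 4, ncol = 0,
              dimnames = list(paste0("d", 1:4), NULL))
  ann <- tibble::tibble(
    id = "d1", category = "C", label = names(priors)[1]
  )
  m <- nb_fit(ann, x, "C", schema, smoothing = 1)
  m$label_prior[] <- priors
  # refresh cached log-likelihood terms after the manual override
  m$.loglik <- NULL
  bayesannot:::finalize_model(m)
}
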
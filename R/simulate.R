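#' A synthetic five-category annotation schema
#'
#' A stand-in schema with the cardinality profile of a cognitive-paradigm
#' annotation ontology: small label inventories for Stimulus Modality (SM,
#' 6), Response Modality (RM, 5) and Response Type (RT, 6), and large ones
#' for Stimulus Type (ST, 25) and Instructions (I, 40), so the
#' many-labels-per-category effect on per-label sample size is reproduced.
#' Every ST label entails its modality in SM (Tone requires Auditory); most
#' RT labels entail a Response Modality (ButtonPress requires Hand); and
#' most Instruction labels entail a Response Modality and a Response Type
#' (Smile requires Facial; PressButton requires Hand and ButtonPress). A few
#' instructions (e.g. RestQuietly) are unrestricted. The label inventories
#' are synthetic: plausible paradigm terms, not a copy of any published
#' ontology release.
#'
#' @return An [onto_schema()] with categories SM, ST, RM, RT, I.
#' @export
default_schema <- function() {
  sm <- c("Visual", "Auditory", "Tactile", "Gustatory", "Olfactory",
          "Interoceptive")
  rm_ <- c("Hand", "Vocal", "Ocular", "Facial", "Foot")
  rt <- c("ButtonPress", "OvertSpeech", "CovertSpeech", "Saccade",
          "JoystickMovement", "FootPress")
  st_map <- c(
    Picture = "Visual", WrittenWord = "Visual", Face = "Visual",
    FlashingCheckerboard = "Visual", FalseFont = "Visual", Shape = "Visual",
    MovingDots = "Visual", LightFlash = "Visual", Letter = "Visual",
    Digit = "Visual", ComplexScene = "Visual", FilmClip = "Visual",
    Symbol = "Visual", PatternMask = "Visual",
    Tone = "Auditory", ChordSequence = "Auditory", SpokenWord = "Auditory",
    WhiteNoise = "Auditory", Melody = "Auditory", Beep = "Auditory",
    Vibration = "Tactile", ThermalProbe = "Tactile",
    TasteSolution = "Gustatory", Odorant = "Olfactory",
    HeartbeatSignal = "Interoceptive"
  )
  rt_map <- c(
    ButtonPress = "Hand", JoystickMovement = "Hand", OvertSpeech = "Vocal",
    Saccade = "Ocular", FootPress = "Foot"
  ) # CovertSpeech is unrestricted
  i_map <- c(
    PressButton = "Hand", PressButtonLeft = "Hand", PressButtonRight = "Hand",
    MoveJoystick = "Hand", PointToTarget = "Hand", DrawShape = "Hand",
    WriteWord = "Hand", TapFinger = "Hand", SqueezeBall = "Hand",
    GraspObject = "Hand", ReleaseButton = "Hand", PressKeySequence = "Hand",
    ReadAloud = "Vocal", NameObject = "Vocal", CountAloud = "Vocal",
    RepeatWord = "Vocal", GenerateVerb = "Vocal", SingNote = "Vocal",
    AnswerQuestion = "Vocal", DescribeScene = "Vocal",
    FixateCross = "Ocular", TrackTarget = "Ocular", MakeSaccade = "Ocular",
    BlinkOnCue = "Ocular",
    Smile = "Facial", Frown = "Facial", RaiseEyebrows = "Facial",
    PuckerLips = "Facial",
    PressPedal = "Foot", TapFoot = "Foot", LiftToe = "Foot"
  )
  i_rt_map <- c(
    PressButton = "ButtonPress", PressButtonLeft = "ButtonPress",
    PressButtonRight = "ButtonPress", TapFinger = "ButtonPress",
    PressKeySequence = "ButtonPress", ReleaseButton = "ButtonPress",
    SqueezeBall = "ButtonPress",
    MoveJoystick = "JoystickMovement", PointToTarget = "JoystickMovement",
    DrawShape = "JoystickMovement", WriteWord = "JoystickMovement",
    GraspObject = "JoystickMovement",
    ReadAloud = "OvertSpeech", NameObject = "OvertSpeech",
    CountAloud = "OvertSpeech", RepeatWord = "OvertSpeech",
    GenerateVerb = "OvertSpeech", SingNote = "OvertSpeech",
    AnswerQuestion = "OvertSpeech", DescribeScene = "OvertSpeech",
    FixateCross = "Saccade", TrackTarget = "Saccade",
    MakeSaccade = "Saccade", BlinkOnCue = "Saccade",
    PressPedal = "FootPress", TapFoot = "FootPress", LiftToe = "FootPress"
  )
  # instructions that presuppose a stimulus modality (reading implies a
  # visual stimulus, pitch discrimination an auditory one)
  i_sm_map <- c(
    ReadAloud = "Visual", NameObject = "Visual", DescribeScene = "Visual",
    DetectTarget = "Visual", TrackTarget = "Visual", FixateCross = "Visual",
    MakeSaccade = "Visual", PointToTarget = "Visual", DrawShape = "Visual",
    DiscriminatePitch = "Auditory", RepeatWord = "Auditory",
    AnswerQuestion = "Auditory", SingNote = "Auditory"
  )
  i_free <- c(
    "AttendStimulus", "RememberItems", "IgnoreDistractor", "RestQuietly",
    "ImagineMovement", "JudgeDuration", "CompareStimuli", "DetectTarget",
    "DiscriminatePitch"
  )
  restrictions <- dplyr::bind_rows(
    tibble::tibble(
      if_label = names(st_map), if_category = "ST",
      then_label = unname(st_map), then_category = "SM"
    ),
    tibble::tibble(
      if_label = names(rt_map), if_category = "RT",
      then_label = unname(rt_map), then_category = "RM"
    ),
    tibble::tibble(
      if_label = names(i_map), if_category = "I",
      then_label = unname(i_map), then_category = "RM"
    ),
    tibble::tibble(
      if_label = names(i_rt_map), if_category = "I",
      then_label = unname(i_rt_map), then_category = "RT"
    ),
    tibble::tibble(
      if_label = names(i_sm_map), if_category = "I",
      then_label = unname(i_sm_map), then_category = "SM"
    )
  )
  onto_schema(
    categories = c("SM", "ST", "RM", "RT", "I"),
    labels = list(
      SM = sm, ST = names(st_map), RM = rm_, RT = rt,
      I = c(names(i_map), i_free)
    ),
    restrictions = restrictions
  )
}

#' Synthetic-corpus generator configuration
#'
#' Captures every knob of the generator that emulates an expert-annotated
#' abstract corpus: the schema, the corpus size (default 247 documents, the
#' size of the motivating expert-annotated collection), mean document length
#' in tokens, the number of signature words carrying each label's signal,
#' the size of the non-informative background vocabulary and its mixture
#' weight, how strongly cross-category entailments are enforced when labels
#' are sampled, and the target mean number of labels per category per
#' document (the per-category geometric rate is `1 / mean_labels`).
#'
#' @param schema An [onto_schema()]; default [default_schema()].
#' @param n_docs Number of documents (default 247).
#' @param words_per_doc Mean Poisson document length in tokens (default 120,
#'   abstract-like).
#' @param vocab_per_label Signature words per label (default 4).
#' @param background_vocab Non-informative background words (default 300).
#' @param background_mix Probability that a token is drawn from the
#'   background distribution rather than from label signal (default 0.7:
#'   most abstract prose is generic methods and context vocabulary, with a
#'   minority of tokens describing the experimental paradigm).
#' @param signature_share Fraction of each label's signature words shared
#'   with a confusable partner label of the same category (default 0.5);
#'   see [label_signature()]. Shared terminology is what makes flat
#'   bag-of-words classification genuinely ambiguous, leaving information
#'   for cross-category dependencies to resolve.
#' @param dependency_strength Overall dependency richness in \[0, 1\]
#'   (default 1). It is the probability that a label draw respects the
#'   schema's entailment restrictions, and it equally scales the latent
#'   paradigm coupling (`paradigm_mix`), so at 0 the label sets of
#'   different categories are fully independent and at 1 entailments always
#'   hold and annotations are strongly paradigm-patterned — the two ways an
#'   expert-curated corpus encodes cross-category dependence (explicitly
#'   stated restrictions, and implicit patterns from coherent experimental
#'   designs).
#' @param n_paradigms Number of latent experiment archetypes (default 25).
#'   Each paradigm is a restriction-consistent bundle of one primary label
#'   per category (a "visual word reading" archetype pairs a written-word
#'   stimulus with vocal responses and a read-aloud instruction); real
#'   corpora are built from such coherent designs, and the patterns they
#'   imprint on the annotations are what ancestor-restricted training sets
#'   can exploit.
#' @param paradigm_mix Probability (before scaling by
#'   `dependency_strength`) that a document's first label in each category
#'   comes from its paradigm's bundle rather than the category's marginal
#'   popularity distribution (default 0.9).
#' @param mean_labels Named numeric vector of target mean labels per
#'   category per document; defaults span 1.15–1.85 across the five default
#'   categories (SM 1.20, ST 1.50, RM 1.15, RT 1.30, I 1.85), 1.3 for other
#'   schemas.
#' @param label_weights Optional named list category -> sampling weight
#'   vector over that category's labels; default Zipf-like `rank^-2`
#'   popularity so a few labels dominate, as in curated corpora.
#' @param seed Integer seed; one seed drives annotation and text sampling
#'   through deterministically split streams.
#' @return A `sim_config` object.
#' @export
sim_config <- function(schema = default_schema(), n_docs = 247,
                       words_per_doc = 120, vocab_per_label = 4,
                       background_vocab = 300, background_mix = 0.7,
                       signature_share = 0.5,
                       dependency_strength = 1, n_paradigms = 25,
                       paradigm_mix = 0.9, mean_labels = NULL,
                       label_weights = NULL, seed = 1) {
  stopifnot(inherits(schema, "onto_schema"))
  stopifnot(n_docs >= 1, dependency_strength >= 0, dependency_strength <= 1)
  stopifnot(words_per_doc > 0, vocab_per_label >= 1, background_vocab >= 0,
            background_mix >= 0, background_mix <= 1,
            signature_share >= 0, signature_share <= 1,
            n_paradigms >= 1, paradigm_mix >= 0, paradigm_mix <= 1)
  if (is.null(mean_labels)) {
    mean_labels <- if (identical(schema$categories,
                                 c("SM", "ST", "RM", "RT", "I"))) {
      c(SM = 1.20, ST = 1.50, RM = 1.15, RT = 1.30, I = 1.85)
    } else {
      stats::setNames(rep(1.3, length(schema$categories)), schema$categories)
    }
  }
  if (!all(schema$categories %in% names(mean_labels)) ||
      any(mean_labels < 1)) {
    stop("mean_labels must name every category, each >= 1", call. = FALSE)
  }
  if (is.null(label_weights)) {
    label_weights <- lapply(schema$labels, function(ll) {
      seq_along(ll)^-2
    })
  }
  structure(
    list(
      schema = schema, n_docs = n_docs, words_per_doc = words_per_doc,
      vocab_per_label = vocab_per_label, background_vocab = background_vocab,
      background_mix = background_mix, signature_share = signature_share,
      dependency_strength = dependency_strength,
      n_paradigms = as.integer(n_paradigms), paradigm_mix = paradigm_mix,
      mean_labels = mean_labels[schema$categories],
      label_weights = label_weights[schema$categories],
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Sample gold-standard annotations
#'
#' Per document and category, draws 1 + Geometric(1 / mean_labels) distinct
#' labels, weighted by the configured label popularity. Categories that are
#' entailment targets are sampled first; each draw in an antecedent category
#' is then, with probability `dependency_strength`, restricted to labels
#' compatible with the document's already-sampled labels (a label is
#' compatible when it has no restriction or its required label is present).
#' If a restricted draw finds no compatible label, a label is drawn from the
#' full pool and its entailed label is forced into the target category, so
#' at `dependency_strength = 1` the output contains no restriction
#' violation. Every category receives at least one label.
#'
#' @param config A [sim_config()].
#' @return A gold-standard annotation tibble (`id`, `category`, `label`).
#' @export
sample_annotations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  schema <- config$schema
  order <- restriction_order(schema) # entailment targets first
  res <- schema$restrictions
  ds <- config$dependency_strength
  pm <- config$paradigm_mix * ds # implicit patterns scale with richness

  # force the entailed labels of `pick`, transitively, so no violation is
  # introduced at full dependency strength
  force_entailments <- function(chosen, pick, cat) {
    frontier <- list(res[res$if_category == cat & res$if_label == pick, ,
                         drop = FALSE])
    while (length(frontier) > 0L) {
      ent <- frontier[[1L]]
      frontier <- frontier[-1L]
      for (i in seq_len(nrow(ent))) {
        tc <- ent$then_category[i]
        tl <- ent$then_label[i]
        if (!tl %in% chosen[[tc]]) {
          chosen[[tc]] <- c(chosen[[tc]], tl)
          nxt <- res[res$if_category == tc & res$if_label == tl, ,
                     drop = FALSE]
          if (nrow(nxt) > 0L) frontier[[length(frontier) + 1L]] <- nxt
        }
      }
    }
    chosen
  }

  # draw k distinct labels for one category into `chosen`, honoring the
  # restriction compatibility coin and an optional paradigm proposal for
  # the first draw
  draw_category <- function(chosen, cat, k, ds_local, proposal = NULL) {
    labs <- schema$labels[[cat]]
    w <- config$label_weights[[cat]]
    rs <- res[res$if_category == cat, , drop = FALSE]
    rows_by_label <- split(seq_len(nrow(rs)), rs$if_label)
    compatible <- function(l) {
      rows <- rows_by_label[[l]]
      is.null(rows) || all(vapply(rows, function(i) {
        rs$then_label[i] %in% chosen[[rs$then_category[i]]]
      }, logical(1)))
    }
    picked <- chosen[[cat]] # may hold labels forced earlier
    first <- TRUE
    while (length(picked) < k) {
      pool <- setdiff(labs, picked)
      if (length(pool) == 0L) break
      force_entailed <- FALSE
      restricted <- nrow(rs) > 0 && stats::runif(1) < ds_local
      pick <- NULL
      if (first && !is.null(proposal) && proposal %in% pool &&
          stats::runif(1) < pm && (!restricted || compatible(proposal))) {
        pick <- proposal
      }
      first <- FALSE
      if (is.null(pick)) {
        if (restricted) {
          ok <- vapply(pool, compatible, logical(1))
          if (any(ok)) {
            pool <- pool[ok]
          } else {
            force_entailed <- TRUE
          }
        }
        pick <- pool[sample.int(length(pool), 1,
                                prob = w[match(pool, labs)])]
      }
      picked <- c(picked, pick)
      if (force_entailed) chosen <- force_entailments(chosen, pick, cat)
    }
    chosen[[cat]] <- picked
    chosen
  }

  empty_chosen <- stats::setNames(
    vector("list", length(schema$categories)), schema$categories
  )

  with_rng_seed(sub_seed(config$seed, 1L), {
    # latent paradigms: restriction-consistent one-label-per-category
    # bundles standing in for coherent experimental designs
    bundles <- lapply(seq_len(config$n_paradigms), function(j) {
      chosen <- empty_chosen
      for (cat in order) {
        chosen <- draw_category(chosen, cat, k = 1L, ds_local = 1)
      }
      lapply(chosen, function(x) x[1])
    })
    w_par <- seq_len(config$n_paradigms)^-1

    rows <- vector("list", config$n_docs)
    for (d in seq_len(config$n_docs)) {
      par <- bundles[[sample.int(config$n_paradigms, 1, prob = w_par)]]
      chosen <- empty_chosen
      for (cat in order) {
        k <- min(
          1L + stats::rgeom(1, 1 / config$mean_labels[[cat]]),
          length(schema$labels[[cat]])
        )
        chosen <- draw_category(chosen, cat, k, ds_local = ds,
                                proposal = par[[cat]])
      }
      rows[[d]] <- tibble::tibble(
        id = sprintf("doc%05d", d),
        category = rep(names(chosen), lengths(chosen)),
        label = unlist(chosen, use.names = FALSE)
      )
    }
  })
  dplyr::bind_rows(rows)
}

#' Signature words of every label
#'
#' Each label carries `vocab_per_label` deterministic signature words (e.g.
#' `stlab03w2`), disjoint from the dedicated background vocabulary
#' `bgword1, bgword2, ...`. A fraction `signature_share` of each label's
#' words is terminology shared with one confusable partner label of the
#' same category — the label half an inventory away, which (by the
#' block-ordered label inventories of [default_schema()]) typically carries
#' a different entailment target. Shared words make labels ambiguous to a
#' flat bag-of-words classifier in exactly the way cross-category ontology
#' context can resolve, emulating overlapping paradigm terminology across
#' sub-fields.
#'
#' @param schema An [onto_schema()].
#' @param vocab_per_label Words per label.
#' @param signature_share Fraction of each label's signature slots drawn
#'   from the shared pair vocabulary (default 0).
#' @return A tibble with columns `category`, `label`, `word`. Shared words
#'   appear once per label that uses them.
#' @export
label_signature <- function(schema, vocab_per_label, signature_share = 0) {
  n_shared <- floor(vocab_per_label * signature_share)
  out <- lapply(schema$categories, function(cat) {
    labs <- schema$labels[[cat]]
    n <- length(labs)
    prefix <- gsub("[^a-z0-9]", "", tolower(cat))
    # symmetric matching i <-> i + floor(n/2); the leftover label of an odd
    # inventory keeps private words in its shared slots
    h <- n %/% 2
    partner <- rep(NA_integer_, n)
    if (h > 0) {
      partner[seq_len(h)] <- seq_len(h) + h
      partner[seq_len(h) + h] <- seq_len(h)
    }
    rows <- lapply(seq_len(n), function(i) {
      word <- character(vocab_per_label)
      for (w in seq_len(vocab_per_label)) {
        if (w <= n_shared && !is.na(partner[i])) {
          pr <- sort(c(i, partner[i]))
          word[w] <- sprintf("%spair%02dx%02dw%d", prefix, pr[1], pr[2], w)
        } else {
          word[w] <- sprintf("%slab%02dw%d", prefix, i, w)
        }
      }
      tibble::tibble(category = cat, label = labs[i], word = word)
    })
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(out)
}

#' Sample document texts from annotated labels
#'
#' Each document's tokens are drawn i.i.d. from a two-part mixture: with
#' probability `background_mix` a uniform draw from the background
#' distribution, otherwise a uniform signature word of one of the
#' document's labels (label chosen uniformly over all its (category, label)
#' assignments). The background distribution is uniform over the dedicated
#' background words *and* every label's signature words, so signature words
#' of labels a document does not carry still appear — but only as background
#' noise, at a much lower rate than true label signal. Document length is
#' Poisson with mean `words_per_doc`.
#'
#' @param annotations A gold-standard annotation tibble.
#' @param config A [sim_config()].
#' @return A document tibble (`id`, `text`).
#' @export
sample_texts <- function(annotations, config) {
  stopifnot(inherits(config, "sim_config"))
  sig <- label_signature(config$schema, config$vocab_per_label,
                         config$signature_share)
  sig_key <- split(
    sig$word, paste(sig$category, sig$label, sep = "\a")
  )
  bg <- c(
    if (config$background_vocab > 0) {
      sprintf("bgword%d", seq_len(config$background_vocab))
    },
    sig$word
  )
  ids <- unique(annotations$id)
  ann_by_doc <- split(
    paste(annotations$category, annotations$label, sep = "\a"),
    factor(annotations$id, levels = ids)
  )
  with_rng_seed(sub_seed(config$seed, 2L), {
    texts <- vapply(ids, function(id) {
      len <- stats::rpois(1, config$words_per_doc)
      if (len == 0L) {
        return("")
      }
      keys <- ann_by_doc[[id]]
      is_bg <- stats::runif(len) < config$background_mix
      if (length(keys) == 0L || length(bg) == 0L) {
        is_bg <- rep(length(keys) == 0L, len)
      }
      tokens <- character(len)
      n_bg <- sum(is_bg)
      if (n_bg > 0) tokens[is_bg] <- sample(bg, n_bg, replace = TRUE)
      n_sig <- len - n_bg
      if (n_sig > 0) {
        key_pick <- keys[sample.int(length(keys), n_sig, replace = TRUE)]
        tokens[!is_bg] <- vapply(key_pick, function(kk) {
          ws <- sig_key[[kk]]
          ws[sample.int(length(ws), 1)]
        }, character(1))
      }
      paste(tokens, collapse = " ")
    }, character(1))
  })
  tibble::tibble(id = ids, text = unname(texts))
}

#' Generate a full synthetic corpus
#'
#' @param config A [sim_config()].
#' @return A list with `documents`, `annotations`, `schema`, `config`.
#' @export
simulate_corpus <- function(config = sim_config()) {
  annotations <- sample_annotations(config)
  documents <- sample_texts(annotations, config)
  list(
    documents = documents, annotations = annotations,
    schema = config$schema, config = config
  )
}

#' Write a corpus (and provenance) to disk
#'
#' Emits `documents.tsv`, `annotations.tsv`, `schema.json` in the package's
#' interchange formats, plus `provenance.json` recording the generator
#' configuration and seed. Round-trips exactly through [load_corpus()].
#'
#' @param corpus A list with `documents`, `annotations`, `schema` (e.g. from
#'   [simulate_corpus()]); a `config` element, if present, is recorded in
#'   the provenance file.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    documents = file.path(dir, "documents.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    schema = file.path(dir, "schema.json")
  )
  write_documents(corpus$documents, paths[["documents"]])
  write_annotations(corpus$annotations, paths[["annotations"]])
  write_schema(corpus$schema, paths[["schema"]])
  if (!is.null(corpus$config)) {
    cfg <- corpus$config
    prov <- cfg[setdiff(names(cfg), "schema")]
    prov$label_weights <- NULL
    jsonlite::write_json(prov, file.path(dir, "provenance.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    paths <- c(paths, provenance = file.path(dir, "provenance.json"))
  }
  invisible(paths)
}

#' Count restriction violations in an annotation set
#'
#' A violation is a (document, restriction) pair where the antecedent label
#' is present and the required label is not.
#'
#' @param annotations An annotation tibble.
#' @param schema An [onto_schema()].
#' @return A tibble with one row per violation (`id`, `if_label`,
#'   `if_category`, `then_label`, `then_category`).
#' @export
restriction_violations <- function(annotations, schema) {
  stopifnot(inherits(schema, "onto_schema"))
  res <- schema$restrictions
  hits <- dplyr::inner_join(
    tibble::as_tibble(annotations), res,
    by = c(category = "if_category", label = "if_label"),
    relationship = "many-to-many" # a label can carry several entailments
  )
  if (nrow(hits) == 0L) {
    return(tibble::tibble(
      id = character(), if_label = character(), if_category = character(),
      then_label = character(), then_category = character()
    ))
  }
  sat <- dplyr::semi_join(
    hits, tibble::as_tibble(annotations),
    by = c(id = "id", then_category = "category", then_label = "label")
  )
  viol <- dplyr::anti_join(
    hits, sat,
    by = c("id", "category", "label", "then_category", "then_label")
  )
  tibble::tibble(
    id = viol$id, if_label = viol$label, if_category = viol$category,
    then_label = viol$then_label, then_category = viol$then_category
  )
}

#' Generative feature probabilities implied by the text model
#'
#' Closed-form P(signature bit TRUE | document has the label) under the
#' token-mixture text model, marginalized over the Poisson length: for a
#' document with L label assignments, each signature word of one of its
#' labels appears with probability 1 - exp(-lambda * q), with
#' q = (1 - background_mix) / (L * vocab_per_label) + background_mix / W,
#' where W is the size of the background pool (dedicated background words
#' plus all distinct signature words). The per-label value averages this
#' over the documents in `annotations` that carry the label; it is the
#' quantity a consistent estimator of P(b | label) must approach as the
#' corpus grows. The closed form holds for the label's *private* signature
#' words; a shared word (see [label_signature()]) can also be emitted by
#' the partner label when both occur in one document, so comparisons
#' against fitted conditionals should use private words.
#'
#' @param annotations A gold-standard annotation tibble.
#' @param config The [sim_config()] that generated (or will generate) texts.
#' @return A tibble with columns `category`, `label`, `prob`, `n_docs`.
#' @export
expected_signature_probability <- function(annotations, config) {
  stopifnot(inherits(config, "sim_config"))
  n_lab <- dplyr::count(tibble::as_tibble(annotations), .data$id,
                        name = "n_labels")
  lam <- config$words_per_doc
  qmul <- (1 - config$background_mix) / config$vocab_per_label
  sig <- label_signature(config$schema, config$vocab_per_label,
                         config$signature_share)
  pool <- config$background_vocab + length(unique(sig$word))
  q_bg <- config$background_mix / pool
  dplyr::inner_join(tibble::as_tibble(annotations), n_lab, by = "id") |>
    dplyr::mutate(p = 1 - exp(-lam * (qmul / .data$n_labels + q_bg))) |>
    dplyr::group_by(.data$category, .data$label) |>
    dplyr::summarise(
      prob = mean(.data$p), n_docs = dplyr::n(), .groups = "drop"
    )
}
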
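#' Tokenize raw text
#'
#' Lowercases, splits on any run of non-alphanumeric characters, and drops
#' pure-number tokens and single-character tokens. This is the minimal
#' reproducible tokenizer for Boolean bag-of-words features; no stemming or
#' lemmatization is applied.
#'
#' @param text Character vector.
#' @return A list of character vectors, one per input element.
#' @export
tokenize <- function(text) {
  toks <- strsplit(tolower(text), "[^[:alnum:]]+")
  lapply(toks, function(tk) {
    tk <- tk[nchar(tk) > 1L]
    tk[!grepl("^[0-9]+$", tk)]
  })
}

#' The packaged English stop-word list
#'
#' A fixed, versioned list of common English function words shipped with the
#' package; tokens on this list never become features.
#'
#' @return Character vector of stop words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "bayesannot")
  readLines(path, encoding = "UTF-8")
}

#' Build the feature vocabulary from a document set
#'
#' Features are the distinct normalized non-stop-word tokens over all
#' documents, in a deterministic (byte-order sorted) order. To avoid
#' train/test leakage, build the vocabulary from training documents only and
#' reuse it for held-out documents; out-of-vocabulary tokens are ignored at
#' featurization time.
#'
#' @param documents Tibble with columns `id`, `text`.
#' @param stopwords Character vector of excluded tokens (default the packaged
#'   English list).
#' @return An object of class `onto_vocabulary`: the ordered feature vector
#'   with the stop-word set attached.
#' @export
build_vocabulary <- function(documents, stopwords = default_stopwords()) {
  toks <- unique(unlist(tokenize(documents$text), use.names = FALSE))
  feats <- sort(setdiff(toks, stopwords), method = "radix")
  structure(
    list(features = feats, stopwords = as.character(stopwords)),
    class = "onto_vocabulary"
  )
}

#' @export
print.onto_vocabulary <- function(x, ...) {
  cat("<onto_vocabulary> ", length(x$features), " features (",
    length(x$stopwords), " stop words excluded)\n",
    sep = ""
  )
  invisible(x)
}

#' Boolean bag-of-words featurization
#'
#' `featurize()` maps a document table to a logical matrix with one row per
#' document and one column per vocabulary feature; bit (c, i) is `TRUE` iff
#' feature i occurs at least once in document c, so word repetition never
#' changes a vector. `vectorize()` is the single-document form.
#'
#' @param documents Tibble with columns `id`, `text`.
#' @param vocab An [build_vocabulary()] result.
#' @return A logical matrix with `rownames` the document ids and `colnames`
#'   the features.
#' @export
featurize <- function(documents, vocab) {
  stopifnot(inherits(vocab, "onto_vocabulary"))
  feats <- vocab$features
  m <- matrix(FALSE,
    nrow = nrow(documents), ncol = length(feats),
    dimnames = list(documents$id, feats)
  )
  toks <- tokenize(documents$text)
  for (i in seq_along(toks)) {
    hit <- match(unique(toks[[i]]), feats)
    m[i, hit[!is.na(hit)]] <- TRUE
  }
  m
}

#' @rdname featurize
#' @param text A single character string.
#' @export
vectorize <- function(text, vocab) {
  stopifnot(length(text) == 1L)
  featurize(tibble::tibble(id = "doc", text = text), vocab)[1L, ]
}
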
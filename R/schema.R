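#' Construct an ontology schema
#'
#' An ontology schema is the flat category/label view of an annotation
#' ontology: an ordered set of categories (e.g. Stimulus Modality, Stimulus
#' Type, Response Modality, Response Type, Instructions), the label inventory
#' of each category, and optional cross-category entailment restrictions such
#' as *Stimulus Type "Tone" requires Stimulus Modality "Auditory"*.
#'
#' @param categories Character vector of unique category names, in order.
#' @param labels Named list mapping each category to a non-empty character
#'   vector of label names (unique within a category).
#' @param restrictions A data frame with columns `if_label`, `if_category`,
#'   `then_label`, `then_category`, one entailment per row, or `NULL` for
#'   none. Every referenced category/label pair must exist in the schema.
#' @return An object of class `onto_schema`.
#' @examples
#' sch <- onto_schema(
#'   categories = c("SM", "ST"),
#'   labels = list(SM = c("Auditory", "Visual"), ST = c("Tone", "Word")),
#'   restrictions = data.frame(
#'     if_label = "Tone", if_category = "ST",
#'     then_label = "Auditory", then_category = "SM"
#'   )
#' )
#' n_labels(sch)
#' @export
onto_schema <- function(categories, labels, restrictions = NULL) {
  categories <- as.character(categories)
  if (length(categories) < 1L) {
    stop("schema must have at least one category", call. = FALSE)
  }
  if (anyDuplicated(categories)) {
    stop("category names must be unique", call. = FALSE)
  }
  if (!setequal(names(labels), categories)) {
    stop("`labels` must have exactly one entry per category", call. = FALSE)
  }
  labels <- lapply(labels[categories], as.character)
  for (cat in categories) {
    if (length(labels[[cat]]) == 0L) {
      stop("category '", cat, "' has no labels", call. = FALSE)
    }
    if (anyDuplicated(labels[[cat]])) {
      stop("labels must be unique within category '", cat, "'", call. = FALSE)
    }
  }
  if (is.null(restrictions)) {
    restrictions <- tibble::tibble(
      if_label = character(), if_category = character(),
      then_label = character(), then_category = character()
    )
  } else {
    restrictions <- tibble::as_tibble(restrictions)[
      , c("if_label", "if_category", "then_label", "then_category")
    ]
    for (i in seq_len(nrow(restrictions))) {
      r <- restrictions[i, ]
      check_label(r$if_category, r$if_label, categories, labels, "restriction antecedent")
      check_label(r$then_category, r$then_label, categories, labels, "restriction consequent")
      if (r$if_category == r$then_category) {
        stop("restrictions must cross categories (row ", i, ")", call. = FALSE)
      }
    }
  }
  structure(
    list(categories = categories, labels = labels, restrictions = restrictions),
    class = "onto_schema"
  )
}

check_label <- function(category, label, categories, labels, what) {
  if (!category %in% categories) {
    stop(what, " references unknown category '", category, "'", call. = FALSE)
  }
  if (!label %in% labels[[category]]) {
    stop(what, " references unknown label '", label, "' in category '",
      category, "'",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' @export
print.onto_schema <- function(x, ...) {
  cat("<onto_schema> ", length(x$categories), " categories, ",
    sum(lengths(x$labels)), " labels, ",
    nrow(x$restrictions), " restrictions\n",
    sep = ""
  )
  for (cat in x$categories) {
    lab <- x$labels[[cat]]
    shown <- paste(utils::head(lab, 5), collapse = ", ")
    if (length(lab) > 5) shown <- paste0(shown, ", ...")
    cat("  ", cat, " (", length(lab), "): ", shown, "\n", sep = "")
  }
  invisible(x)
}

#' Label counts per category
#'
#' @param schema An [onto_schema()].
#' @return A tibble with columns `category` and `n_labels`.
#' @export
n_labels <- function(schema) {
  stopifnot(inherits(schema, "onto_schema"))
  tibble::tibble(
    category = schema$categories,
    n_labels = unname(lengths(schema$labels[schema$categories]))
  )
}

#' Read / write an ontology schema as JSON
#'
#' The on-disk form is a JSON object with members `categories` (array),
#' `labels` (object mapping category to label array) and `restrictions`
#' (array of objects with `if_label`, `if_category`, `then_label`,
#' `then_category`).
#'
#' @param path File path.
#' @return `read_schema()` returns an [onto_schema()]; `write_schema()`
#'   returns `path` invisibly.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) {
      stop("failed to parse schema JSON '", path, "': ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  if (is.null(raw$categories) || is.null(raw$labels)) {
    stop("schema JSON must contain 'categories' and 'labels'", call. = FALSE)
  }
  restrictions <- raw$restrictions
  if (!is.null(restrictions) && length(restrictions) == 0L) restrictions <- NULL
  onto_schema(raw$categories, raw$labels, restrictions)
}

#' @rdname read_schema
#' @param schema An [onto_schema()].
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "onto_schema"))
  obj <- list(
    categories = schema$categories,
    labels = schema$labels,
    restrictions = schema$restrictions
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE, digits = NA)
  invisible(path)
}

# category-level entailment graph must be acyclic for the generator's
# dependency-respecting sampling order to exist
restriction_order <- function(schema) {
  res <- schema$restrictions
  cats <- schema$categories
  if (nrow(res) == 0L) {
    return(cats)
  }
  # edge then_category -> if_category: targets must be sampled first
  edges <- unique(res[, c("then_category", "if_category")])
  ordered <- character(0)
  remaining <- cats
  while (length(remaining) > 0L) {
    # a category is ready when every category it depends on is already placed
    deps <- lapply(remaining, function(cc) {
      edges$then_category[edges$if_category == cc]
    })
    ready <- remaining[vapply(deps, function(d) all(d %in% ordered), logical(1))]
    if (length(ready) == 0L) {
      stop("restrictions form a cycle across categories", call. = FALSE)
    }
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  ordered
}
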
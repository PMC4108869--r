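#' Read and write document and annotation tables
#'
#' Documents travel as a TSV with header `id<TAB>text`, one abstract per row;
#' annotations as a TSV with header `id<TAB>category<TAB>label`, one
#' (document, label) assignment per row. Both are UTF-8. Tabs and newlines
#' inside text are flattened to spaces on write so the dialect stays
#' single-line.
#'
#' @param path File path.
#' @return `read_documents()` returns a tibble with columns `id`, `text`;
#'   `read_annotations()` a tibble with columns `id`, `category`, `label`.
#' @export
read_documents <- function(path) {
  df <- read_tsv_checked(path, c("id", "text"))
  if (anyDuplicated(df$id)) {
    stop("duplicate document id: ", df$id[duplicated(df$id)][1], call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname read_documents
#' @export
read_annotations <- function(path) {
  tibble::as_tibble(read_tsv_checked(path, c("id", "category", "label")))
}

read_tsv_checked <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.delim(path,
      sep = "\t", quote = "", header = TRUE,
      colClasses = "character", encoding = "UTF-8",
      blank.lines.skip = FALSE, stringsAsFactors = FALSE
    ),
    error = function(e) {
      stop("failed to parse TSV '", path, "': ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  if (!identical(names(df), columns)) {
    stop("'", path, "': expected header ", paste(columns, collapse = "\t"),
      " (line 1)",
      call. = FALSE
    )
  }
  bad <- which(!stats::complete.cases(df))
  if (length(bad) > 0) {
    stop("'", path, "': malformed row at line ", bad[1] + 1L, call. = FALSE)
  }
  df
}

#' @rdname read_documents
#' @param documents Tibble with columns `id`, `text`.
#' @export
write_documents <- function(documents, path) {
  documents <- tibble::as_tibble(documents)[, c("id", "text")]
  documents$text <- gsub("[\t\r\n]+", " ", documents$text)
  utils::write.table(documents, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' @rdname read_documents
#' @param annotations Tibble with columns `id`, `category`, `label`.
#' @export
write_annotations <- function(annotations, path) {
  annotations <- tibble::as_tibble(annotations)[, c("id", "category", "label")]
  utils::write.table(annotations, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Validate an annotation table against a schema
#'
#' Checks that every (category, label) pair exists in the schema, that every
#' annotated id is a known document, and (for gold-standard sets) that every
#' document carries at least one label in every category.
#'
#' @param annotations Tibble with columns `id`, `category`, `label`.
#' @param schema An [onto_schema()].
#' @param documents Optional tibble of documents; if given, annotation ids
#'   must be a subset of document ids.
#' @param gold If `TRUE`, enforce the gold-standard completeness invariant
#'   (at least one label per category per document). Predicted sets may be
#'   empty per category and are validated with `gold = FALSE`.
#' @return The annotations, invisibly, if valid; otherwise an error naming
#'   the first offender.
#' @export
validate_annotations <- function(annotations, schema, documents = NULL,
                                 gold = FALSE) {
  stopifnot(inherits(schema, "onto_schema"))
  annotations <- tibble::as_tibble(annotations)
  bad_cat <- setdiff(unique(annotations$category), schema$categories)
  if (length(bad_cat) > 0) {
    stop("unknown category '", bad_cat[1], "' in annotations", call. = FALSE)
  }
  for (cat in unique(annotations$category)) {
    bad <- setdiff(annotations$label[annotations$category == cat],
                   schema$labels[[cat]])
    if (length(bad) > 0) {
      stop("unknown label '", bad[1], "' for category '", cat, "'",
        call. = FALSE
      )
    }
  }
  if (!is.null(documents)) {
    orphan <- setdiff(unique(annotations$id), documents$id)
    if (length(orphan) > 0) {
      stop("annotation references unknown document id '", orphan[1], "'",
        call. = FALSE
      )
    }
    if (gold && nrow(documents) > 0) {
      have <- dplyr::distinct(annotations, .data$id, .data$category)
      need <- tidyr::expand_grid(id = documents$id, category = schema$categories)
      miss <- dplyr::anti_join(need, have, by = c("id", "category"))
      if (nrow(miss) > 0) {
        stop("gold standard incomplete: document '", miss$id[1],
          "' has no label in category '", miss$category[1], "'",
          call. = FALSE
        )
      }
    }
  }
  invisible(annotations)
}

#' Load a corpus triple from disk
#'
#' Reads the documents TSV, annotations TSV and schema JSON, and validates
#' annotations against both the schema and the document table.
#'
#' @param documents_path,annotations_path,schema_path File paths (see
#'   [read_documents()] and [read_schema()] for formats).
#' @param gold Enforce gold-standard completeness (default `TRUE`); see
#'   [validate_annotations()].
#' @return A list with elements `documents`, `annotations`, `schema`.
#' @export
load_corpus <- function(documents_path, annotations_path, schema_path,
                        gold = TRUE) {
  documents <- read_documents(documents_path)
  annotations <- read_annotations(annotations_path)
  schema <- read_schema(schema_path)
  validate_annotations(annotations, schema, documents, gold = gold)
  list(documents = documents, annotations = annotations, schema = schema)
}
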
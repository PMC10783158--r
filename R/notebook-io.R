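# Reading and writing ipynb documents.
#
# An ipynb file is JSON; we keep the parsed document as a nested list mirroring
# the nbformat schema (v4). Version-3 documents carry their cells inside
# "worksheets"; they are flattened to a single cell list on read and cell-type
# aliases ("heading") are mapped onto the v4 vocabulary.

#' Read a notebook document
#'
#' Parses an ipynb JSON file into a nested list following the nbformat v4
#' layout. Version-3 documents are upgraded on read: worksheets are flattened
#' into one cell list, `input` becomes `source`, and `heading` cells become
#' Markdown. Cell sources are normalized to a single string.
#'
#' @param path Path to an `.ipynb` file.
#' @return A list with elements `nbformat`, `nbformat_minor`, `metadata`, and
#'   `cells`, or an object of class `nb_parse_failure` when the file is not
#'   valid JSON or lacks the notebook schema's mandatory shape.
#' @export
read_notebook <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) NULL
  )
  if (is.null(doc) || !is.list(doc)) {
    return(structure(list(path = path, status = "invalid_json"),
                     class = "nb_parse_failure"))
  }
  nbformat <- doc$nbformat %||% NA_integer_
  if (!is.null(doc$worksheets)) {
    # v3: flatten worksheets into one cell list
    cells <- list()
    for (ws in doc$worksheets) cells <- c(cells, ws$cells %||% list())
    cells <- lapply(cells, upgrade_v3_cell)
    doc$cells <- cells
    doc$worksheets <- NULL
  }
  if (is.null(doc$cells) || !is.list(doc$cells)) {
    return(structure(list(path = path, status = "invalid_schema"),
                     class = "nb_parse_failure"))
  }
  ok <- vapply(doc$cells, function(cell) {
    is.list(cell) && is_string(cell$cell_type %||% NA_character_)
  }, logical(1))
  if (length(ok) && !all(ok)) {
    return(structure(list(path = path, status = "invalid_schema"),
                     class = "nb_parse_failure"))
  }
  doc$cells <- lapply(doc$cells, function(cell) {
    cell$source <- collapse_source(cell$source)
    cell
  })
  doc$nbformat <- as.integer(nbformat)
  doc
}

upgrade_v3_cell <- function(cell) {
  type <- cell$cell_type %||% "code"
  if (identical(type, "heading")) {
    level <- cell$level %||% 1L
    cell$cell_type <- "markdown"
    cell$source <- paste0(strrep("#", level), " ", collapse_source(cell$source))
  }
  if (!is.null(cell$input)) {
    cell$source <- cell$input
    cell$input <- NULL
  }
  if (!is.null(cell$prompt_number)) {
    cell$execution_count <- cell$prompt_number
    cell$prompt_number <- NULL
  }
  cell
}

#' @rdname read_notebook
#' @param x Object returned by [read_notebook()].
#' @export
is_parse_failure <- function(x) inherits(x, "nb_parse_failure")

empty_json_object <- function() structure(list(), names = character(0))

#' Write a notebook document
#'
#' Serializes a notebook list (as produced by [read_notebook()] or the forge)
#' back to ipynb JSON. Output is deterministic for a given document, which the
#' forge relies on for byte-stable corpora.
#'
#' @param nb Notebook document list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_notebook <- function(nb, path) {
  nb$metadata <- nb$metadata %||% empty_json_object()
  if (length(nb$metadata) == 0L) nb$metadata <- empty_json_object()
  nb$cells <- lapply(nb$cells, function(cell) {
    cell$metadata <- cell$metadata %||% empty_json_object()
    if (length(cell$metadata) == 0L) cell$metadata <- empty_json_object()
    if (identical(cell$cell_type, "code")) {
      cell$outputs <- cell$outputs %||% list()
    }
    cell
  })
  json <- jsonlite::toJSON(nb, auto_unbox = TRUE, null = "null", digits = NA,
                           pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

# Convenience constructors used by the forge and tests.
nb_code_cell <- function(source, outputs = list(), execution_count = NULL) {
  list(cell_type = "code", metadata = empty_json_object(), source = source,
       outputs = outputs, execution_count = execution_count)
}

nb_markdown_cell <- function(source) {
  list(cell_type = "markdown", metadata = empty_json_object(), source = source)
}

nb_raw_cell <- function(source) {
  list(cell_type = "raw", metadata = empty_json_object(), source = source)
}

nb_stream_output <- function(text, name = "stdout") {
  list(output_type = "stream", name = name, text = text)
}

new_notebook <- function(cells, kernel_name = "python3", language = "python",
                         language_version = "3.11") {
  metadata <- empty_json_object()
  if (!is.null(kernel_name)) {
    metadata <- list(
      kernelspec = list(name = kernel_name,
                        display_name = kernel_name,
                        language = language)
    )
    if (!is.null(language_version)) {
      metadata$language_info <- list(name = language, version = language_version)
    }
  }
  list(nbformat = 4L, nbformat_minor = 5L, metadata = metadata, cells = cells)
}
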
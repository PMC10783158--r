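# Static notebook census: structure, Markdown profile, name portability.

#' Profile the structure of a notebook
#'
#' Counts cells by type, empty cells (source empty or whitespace-only,
#' regardless of type), cells with stored outputs, and the maximum execution
#' count. Language resolution order: kernelspec language, else
#' `language_info$name`, else `"unknown"`; the interpreter version comes from
#' `language_info$version`. When kernelspec and language_info disagree the
#' kernelspec wins and the disagreement is flagged.
#'
#' @param nb A parsed notebook document from [read_notebook()].
#' @return A list of class `notebook_structure`.
#' @export
profile_structure <- function(nb) {
  stopifnot(!is_parse_failure(nb))
  cells <- nb$cells %||% list()
  types <- vapply(cells, function(c) c$cell_type %||% "code", character(1))
  sources <- vapply(cells, function(c) c$source %||% "", character(1))

  kernel_lang <- nb$metadata$kernelspec$language
  info_lang <- nb$metadata$language_info$name
  language <- tolower(kernel_lang %||% info_lang %||% "unknown")
  lang_disagrees <- !is.null(kernel_lang) && !is.null(info_lang) &&
    tolower(kernel_lang) != tolower(info_lang)

  version <- nb$metadata$language_info$version
  version <- if (is.null(version)) NA_character_ else as.character(version)
  major <- if (is.na(version)) NA_integer_ else
    suppressWarnings(as.integer(strsplit(version, ".", fixed = TRUE)[[1]][1]))

  counts <- vapply(cells, function(c) {
    ec <- c$execution_count
    if (is.null(ec) || is.na(suppressWarnings(as.numeric(ec)))) NA_real_
    else as.numeric(ec)
  }, numeric(1))
  has_counts <- any(!is.na(counts))

  out_n <- vapply(cells, function(c) {
    identical(c$cell_type, "code") && length(c$outputs %||% list()) > 0L
  }, logical(1))

  structure(list(
    nbformat_version = c(nb$nbformat %||% NA_integer_,
                         nb$nbformat_minor %||% NA_integer_),
    kernel_name = nb$metadata$kernelspec$name %||% NA_character_,
    language = language,
    language_disagreement = lang_disagrees,
    language_version_full = version,
    major_version = major,
    cells_total = length(cells),
    code_cells = sum(types == "code"),
    markdown_cells = sum(types == "markdown"),
    raw_cells = sum(types == "raw"),
    empty_cells = sum(!nzchar(trimws(sources))),
    cells_with_output = sum(out_n),
    max_execution_count = if (has_counts) max(counts, na.rm = TRUE) else NA_real_,
    has_execution_counts = has_counts
  ), class = "notebook_structure")
}

#' Default natural-language detector
#'
#' A small stopword-frequency classifier over a handful of languages
#' (English, French, German, Spanish, Danish). Returns a two-letter code, or
#' `"undetected"` for short or unclassifiable text. Any detector with the
#' same `text -> code` interface can be injected into [profile_markdown()].
#'
#' @param text A character string.
#' @return A language code or `"undetected"`.
#' @export
detect_language_stopwords <- function(text) {
  words <- tolower(unlist(strsplit(gsub("[^\\p{L} ]", " ", text, perl = TRUE), "\\s+")))
  words <- words[nzchar(words)]
  if (length(words) < 3L) return("undetected")
  stopsets <- list(
    en = c("the", "and", "of", "to", "in", "is", "that", "for", "with", "this",
           "are", "was", "from", "which", "results"),
    fr = c("le", "la", "les", "et", "des", "est", "dans", "pour", "une", "un",
           "que", "avec", "sur", "nous"),
    de = c("der", "die", "das", "und", "ist", "nicht", "mit", "ein", "eine",
           "den", "von", "zu"),
    es = c("el", "los", "las", "es", "en", "por", "para", "con", "una", "del",
           "se", "como"),
    da = c("og", "det", "er", "til", "af", "den", "ikke", "som", "med")
  )
  hits <- vapply(stopsets, function(sw) sum(words %in% sw), numeric(1))
  if (max(hits) < 2 || max(hits) / length(words) < 0.05) return("undetected")
  names(which.max(hits))
}

#' Profile the Markdown cells of a notebook
#'
#' Detects the Markdown elements present (ATX/Setext headers, paragraphs,
#' list markers, fenced code blocks, links, images, tables), counts lines and
#' words, and applies the injected natural-language detector to each
#' Markdown cell, reporting the union of detected languages.
#'
#' @param nb A parsed notebook document.
#' @param lang_detector A `text -> language code` function; defaults to
#'   [detect_language_stopwords()].
#' @return A list of class `markdown_profile` with `languages_detected`,
#'   `english_only`, `total_lines`, `total_words`, `elements_present`.
#' @export
profile_markdown <- function(nb, lang_detector = detect_language_stopwords) {
  stopifnot(!is_parse_failure(nb))
  md <- Filter(function(c) identical(c$cell_type, "markdown"), nb$cells %||% list())
  texts <- vapply(md, function(c) c$source %||% "", character(1))
  all_lines <- unlist(lapply(texts, split_lines))
  words <- unlist(strsplit(paste(texts, collapse = " "), "\\s+"))
  words <- words[nzchar(words)]

  elements <- character(0)
  lines <- all_lines %||% character(0)
  in_fence <- FALSE
  prose <- character(0)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*(```|~~~)", ln)) { in_fence <- !in_fence
      elements <- c(elements, "code_block"); next }
    if (in_fence) next
    if (grepl("^#{1,6}\\s", ln)) { elements <- c(elements, "header"); next }
    if (i > 1 && grepl("^(=+|-+)\\s*$", ln) && nzchar(trimws(lines[i - 1]))) {
      elements <- c(elements, "header"); next
    }
    if (grepl("^\\s*([-*+]|\\d+[.)])\\s+", ln)) { elements <- c(elements, "list"); next }
    if (grepl("^\\s*\\|.*\\|\\s*$", ln)) { elements <- c(elements, "table"); next }
    if (grepl("!\\[[^]]*\\]\\(", ln)) elements <- c(elements, "image")
    if (grepl("(^|[^!])\\[[^]]+\\]\\(", ln)) elements <- c(elements, "link")
    if (nzchar(trimws(ln))) prose <- c(prose, ln)
  }
  if (length(prose) > 0L) elements <- c(elements, "paragraph")
  elements <- sort(unique(elements))

  langs <- unique(vapply(texts, lang_detector, character(1), USE.NAMES = FALSE))
  langs <- setdiff(langs, "undetected")
  if (length(words) == 0L || length(langs) == 0L) langs_out <- "undetected"
  else langs_out <- langs

  structure(list(
    languages_detected = langs_out,
    english_only = identical(langs_out, "en"),
    total_lines = length(lines),
    total_words = length(words),
    elements_present = elements
  ), class = "markdown_profile")
}

WINDOWS_RESERVED <- c("CON", "PRN", "AUX", "NUL",
                      paste0("COM", 1:9), paste0("LPT", 1:9))

#' Profile a notebook's file name
#'
#' Computes the title (final path segment minus the `.ipynb` extension), its
#' length, POSIX fully-portable-filename conformance (characters restricted
#' to `[A-Za-z0-9._-]`, not starting with `-`; the historic 14-character
#' limit is reported as a separate flag, not a violation), Windows-disallowed
#' names (reserved device names or the characters `<>:"/\|?*`), and the
#' "Untitled" / "Copy" / "test" markers (the latter two case-insensitive
#' substring matches).
#'
#' @param relative_path Path string ending in `.ipynb`.
#' @return A list of class `naming_profile`.
#' @export
profile_name <- function(relative_path) {
  stopifnot(grepl("\\.ipynb$", relative_path))
  title <- sub("\\.ipynb$", "", basename(relative_path))
  stopifnot(nchar(title) >= 1L)
  posix <- grepl("^[A-Za-z0-9._-]+$", title) && !startsWith(title, "-")
  win_bad <- toupper(title) %in% WINDOWS_RESERVED ||
    grepl('[<>:"/\\\\|?*]', title)
  structure(list(
    title = title,
    title_length = nchar(title),
    posix_portable = posix,
    exceeds_14_chars = nchar(title) > 14L,
    windows_disallowed = win_bad,
    is_untitled = startsWith(title, "Untitled"),
    contains_copy = grepl("copy", title, ignore.case = TRUE),
    contains_test = grepl("test", title, ignore.case = TRUE)
  ), class = "naming_profile")
}
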
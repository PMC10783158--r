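# Import profiling of Python notebooks via the language's own AST.

#' Strip notebook shell directives from a code cell
#'
#' Lines starting with `%` (line/cell magics) or `!` (shell escapes) and
#' lines ending in `?` (help queries) are not part of the language grammar;
#' they are removed before parsing and returned separately so nothing is
#' lost. `%load_ext` extensions are singled out because they matter for
#' reproducibility.
#'
#' @param source A code-cell source string.
#' @return A list with `code` (cleaned source), `directives` (the removed
#'   lines), and `load_extensions` (names passed to `%load_ext`).
#' @export
strip_directives <- function(source) {
  lines <- split_lines(source)
  is_directive <- grepl("^\\s*[%!]", lines) | grepl("\\?\\s*$", lines)
  directives <- lines[is_directive]
  ext <- regmatches(directives,
                    regexec("^\\s*%load_ext\\s+([A-Za-z0-9_.]+)", directives))
  load_ext <- vapply(ext, function(m) if (length(m) == 2L) m[2] else NA_character_,
                     character(1))
  load_ext <- load_ext[!is.na(load_ext)]
  lines[is_directive] <- ""
  list(code = paste(lines, collapse = "\n"),
       directives = directives,
       load_extensions = load_ext)
}

# Run the AST helper over a list of cleaned sources; one python call per
# notebook, not per cell.
parse_cells_ast <- function(sources) {
  if (length(sources) == 0L) return(list())
  payload <- jsonlite::toJSON(list(cells = sources), auto_unbox = FALSE)
  out <- system2(nbaudit_python(), shQuote(python_helper("extract_imports.py")),
                 input = as.character(payload), stdout = TRUE, stderr = FALSE)
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}

# All module-file stems and directory names under a repository root, used to
# decide whether an import is local.
local_module_names <- function(repo_root) {
  files <- list.files(repo_root, recursive = TRUE, all.files = FALSE,
                      include.dirs = TRUE, no.. = TRUE)
  py <- files[grepl("\\.py$", files)]
  stems <- sub("\\.py$", "", basename(py))
  dirs <- basename(files[dir.exists(file.path(repo_root, files))])
  unique(c(stems, dirs))
}

#' Profile the imports of a Python notebook
#'
#' Strips shell directives, parses every code cell with the Python abstract
#' syntax tree, and classifies each imported module as local (its top-level
#' name resolves to a module file or package directory anywhere under
#' `repo_root`, or it is a relative import) or external. Function and class
#' definitions are counted across cells. A cell that fails to parse sets
#' `syntax_ok = FALSE` and is skipped; the remaining cells still contribute
#' (per-cell best effort).
#'
#' @param nb A parsed notebook document.
#' @param repo_root Repository working tree used for local-import resolution.
#' @return A list of class `import_profile` with multisets `modules_external`
#'   and `modules_local` (character vectors with duplicates preserved),
#'   `functions_defined`, `classes_defined`, `load_extensions`, `syntax_ok`.
#' @export
profile_imports <- function(nb, repo_root) {
  stopifnot(!is_parse_failure(nb))
  code_cells <- Filter(function(c) identical(c$cell_type, "code"),
                       nb$cells %||% list())
  stripped <- lapply(code_cells, function(c) strip_directives(c$source %||% ""))
  load_ext <- unlist(lapply(stripped, `[[`, "load_extensions")) %||% character(0)
  sources <- vapply(stripped, `[[`, character(1), "code")

  parsed <- parse_cells_ast(sources)
  locals_avail <- local_module_names(repo_root)

  ext_mods <- character(0); loc_mods <- character(0)
  functions <- 0L; classes <- 0L; syntax_ok <- TRUE
  for (cell in parsed) {
    if (!isTRUE(cell$ok)) { syntax_ok <- FALSE; next }
    functions <- functions + cell$functions
    classes <- classes + cell$classes
    for (imp in cell$imports) {
      mod <- imp$module
      top <- if (nzchar(mod)) strsplit(mod, ".", fixed = TRUE)[[1]][1] else ""
      if (imp$level > 0L || (nzchar(top) && top %in% locals_avail)) {
        loc_mods <- c(loc_mods, if (nzchar(mod)) mod else ".")
      } else if (nzchar(mod)) {
        ext_mods <- c(ext_mods, mod)
      }
    }
  }
  # a name cannot be both: local resolution wins
  ext_mods <- ext_mods[!(ext_mods %in% loc_mods)]
  structure(list(
    modules_external = ext_mods,
    modules_local = loc_mods,
    functions_defined = functions,
    classes_defined = classes,
    load_extensions = load_ext,
    syntax_ok = syntax_ok
  ), class = "import_profile")
}
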
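# Code-style findings for notebook code cells.
#
# The default engine is a compact checker for the PEP 8 codes that dominate
# notebook corpora (whitespace after commas, whitespace around operators,
# comment formatting, late imports, trailing semicolons, multiple
# imports/statements per line, trailing whitespace). It is injectable: any
# engine with the `code text -> findings data.frame` interface can replace it.

STYLE_DESCRIPTIONS <- c(
  E225 = "missing whitespace around operator",
  E231 = "missing whitespace after ',', ';', or ':'",
  E262 = "inline comment should start with '# '",
  E265 = "block comment should start with '# '",
  E401 = "multiple imports on one line",
  E402 = "module level import not at top of file",
  E701 = "multiple statements on one line (colon)",
  E703 = "statement ends with a semicolon",
  W291 = "trailing whitespace"
)

# Mask string literals (and separate out comments) so that the line-based
# checks never fire inside strings. Handles single/double quotes, escapes,
# and triple-quoted strings spanning lines. Returns data.frame(code, comment).
mask_strings <- function(lines) {
  in_triple <- FALSE; triple_q <- ""
  code <- character(length(lines)); comment <- character(length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[i]
    chars <- strsplit(ln, "")[[1]]
    out <- chars
    cmt <- ""
    j <- 1L
    in_str <- FALSE; q <- ""
    while (j <= length(chars)) {
      ch <- chars[j]
      if (in_triple) {
        if (ch == triple_q && j + 2L <= length(chars) &&
            chars[j + 1L] == triple_q && chars[j + 2L] == triple_q) {
          out[j:(j + 2L)] <- "s"; j <- j + 3L; in_triple <- FALSE; next
        }
        out[j] <- "s"; j <- j + 1L; next
      }
      if (in_str) {
        if (ch == "\\") { out[j] <- "s"; if (j < length(chars)) out[j + 1L] <- "s"
          j <- j + 2L; next }
        if (ch == q) in_str <- FALSE
        out[j] <- "s"; j <- j + 1L; next
      }
      if (ch == "#") {
        cmt <- paste(chars[j:length(chars)], collapse = "")
        out <- out[seq_len(j - 1L)]
        break
      }
      if (ch == "'" || ch == "\"") {
        if (j + 2L <= length(chars) && chars[j + 1L] == ch && chars[j + 2L] == ch) {
          out[j:(j + 2L)] <- "s"; in_triple <- TRUE; triple_q <- ch; j <- j + 3L; next
        }
        in_str <- TRUE; q <- ch; out[j] <- "s"; j <- j + 1L; next
      }
      j <- j + 1L
    }
    if (in_triple && length(out) == length(chars)) {
      # whole remainder of the line is inside the triple string
    }
    code[i] <- paste(out, collapse = "")
    comment[i] <- cmt
  }
  data.frame(code = code, comment = comment, stringsAsFactors = FALSE)
}

finding <- function(code, line, column) {
  data.frame(code = code,
             description = unname(STYLE_DESCRIPTIONS[code]),
             line = line, column = column, stringsAsFactors = FALSE)
}

# depth of parens/brackets/braces before each character of a masked line,
# continued across lines is not tracked (cell-local, line-based heuristic)
paren_depth_before <- function(chars) {
  depth <- integer(length(chars))
  d <- 0L
  for (i in seq_along(chars)) {
    depth[i] <- d
    if (chars[i] %in% c("(", "[", "{")) d <- d + 1L
    if (chars[i] %in% c(")", "]", "}")) d <- max(0L, d - 1L)
  }
  depth
}

#' Default style engine
#'
#' Checks one code-cell source string against a compact subset of the PEP 8
#' rules and returns all findings, none suppressed. Strings and comments are
#' masked before the whitespace checks so findings never point inside
#' literals.
#'
#' @param code A code-cell source string (directives already stripped or not;
#'   magic lines are ignored).
#' @return A data.frame with columns `code`, `description`, `line`, `column`
#'   (cell-local, 1-based).
#' @export
style_engine_default <- function(code) {
  lines <- split_lines(code)
  findings <- list()
  add <- function(f) findings[[length(findings) + 1L]] <<- f
  if (length(lines) == 0L) return(finding(character(0), integer(0), integer(0)))
  magic <- grepl("^\\s*[%!]", lines)
  masked <- mask_strings(ifelse(magic, "", lines))
  seen_code <- FALSE

  for (i in seq_along(lines)) {
    if (magic[i]) next
    code_ln <- masked$code[i]
    cmt <- masked$comment[i]
    chars <- strsplit(code_ln, "")[[1]]
    depth <- paren_depth_before(chars)
    has_code <- nzchar(trimws(code_ln))

    # W291 trailing whitespace
    if (grepl("[ \t]+$", lines[i]) && (has_code || nzchar(cmt))) {
      add(finding("W291", i, nchar(sub("[ \t]+$", "", lines[i])) + 1L))
    }

    # comment formatting
    if (nzchar(cmt)) {
      proper <- grepl("^# ", cmt) || identical(cmt, "#") || startsWith(cmt, "#!")
      col <- nchar(code_ln) + 1L
      if (!has_code && !proper) add(finding("E265", i, col))
      if (has_code && (!proper || startsWith(cmt, "##")))
        add(finding("E262", i, col))
    }

    # E231: ',' or ';' not followed by whitespace (or end of line/closing)
    for (m in gregexpr("[,;](?=[^\\s)\\]}])", code_ln, perl = TRUE)[[1]]) {
      if (m > 0) add(finding("E231", i, m))
    }

    # E225: two-character comparison/augmented operators without spaces,
    # bare '=' at bracket depth 0, and tight comparisons like a<b
    for (op in c("==", "!=", "<=", ">=", "->", "\\+=", "-=", "\\*=", "/=")) {
      pat <- paste0("(\\S", op, ")|(", op, "\\S)")
      for (m in gregexpr(paste0("\\S", op, "|", op, "\\S"), code_ln, perl = TRUE)[[1]]) {
        if (m > 0) { add(finding("E225", i, m + 1L)); break }
      }
    }
    eq <- gregexpr("(?<![=!<>+*/\\-])=(?!=)", code_ln, perl = TRUE)[[1]]
    for (m in eq) {
      if (m <= 0) next
      if (m <= length(depth) && depth[m] > 0L) next  # keyword argument (E251 domain)
      left_tight <- m > 1L &&
        grepl("[A-Za-z0-9_)\\]]", substr(code_ln, m - 1L, m - 1L), perl = TRUE)
      right_tight <- m < nchar(code_ln) &&
        grepl("[A-Za-z0-9_(\"'s\\[-]", substr(code_ln, m + 1L, m + 1L), perl = TRUE)
      if (left_tight && right_tight) add(finding("E225", i, m))
    }

    # E401: import a, b
    if (grepl("^\\s*import\\s+[A-Za-z0-9_.]+\\s*,", code_ln))
      add(finding("E401", i, regexpr(",", code_ln, fixed = TRUE)))

    # E402: import after code at top level of the cell
    is_import <- grepl("^(import|from)\\s", code_ln)
    if (is_import && seen_code && !grepl("__future__", code_ln))
      add(finding("E402", i, 1L))
    if (has_code && !is_import) seen_code <- TRUE

    # E701: compound statement with body on the same line
    if (grepl("^\\s*(if|elif|else|for|while|with|try|except|finally|def|class)\\b", code_ln)) {
      colon <- regexpr(":(?!=)", code_ln, perl = TRUE)
      if (colon > 0) {
        rest <- substr(code_ln, colon + 1L, nchar(code_ln))
        if (nzchar(trimws(rest))) add(finding("E701", i, colon))
      }
    }

    # E703: statement ends with a semicolon
    stripped <- sub("\\s+$", "", code_ln)
    if (nzchar(stripped) && endsWith(stripped, ";"))
      add(finding("E703", i, nchar(stripped)))
  }
  if (length(findings) == 0L) return(finding(character(0), integer(0), integer(0)))
  do.call(rbind, findings)
}

#' Profile the code style of a notebook
#'
#' Runs the style engine over every code cell and returns all findings with
#' cell-local coordinates. An engine failure on one cell skips that cell.
#'
#' @param nb A parsed notebook document.
#' @param style_engine A `code text -> findings data.frame` function;
#'   defaults to [style_engine_default()].
#' @return A data.frame with columns `cell_index` (0-based, over all cells),
#'   `code`, `description`, `line`, `column`.
#' @export
profile_style <- function(nb, style_engine = style_engine_default) {
  stopifnot(!is_parse_failure(nb))
  cells <- nb$cells %||% list()
  rows <- list()
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    if (!identical(cell$cell_type, "code")) next
    f <- tryCatch(style_engine(cell$source %||% ""), error = function(e) NULL)
    if (is.null(f) || nrow(f) == 0L) next
    f$cell_index <- i - 1L
    rows[[length(rows) + 1L]] <- f
  }
  if (length(rows) == 0L) {
    return(data.frame(code = character(0), description = character(0),
                      line = integer(0), column = integer(0),
                      cell_index = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  stopifnot(all(grepl("^[EWF][0-9]+$", out$code)))
  out
}
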
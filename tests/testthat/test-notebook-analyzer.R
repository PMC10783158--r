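# Static notebook census: structure, Markdown, naming, imports, style.

# Independent recount: walk the raw JSON with jsonlite, without the package's
# reader, and tally the structural census.
brute_force_recount <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cells <- raw$cells
  if (!is.null(raw$worksheets)) {
    cells <- do.call(c, lapply(raw$worksheets, `[[`, "cells"))
  }
  type_of <- function(cell) {
    t <- cell$cell_type
    if (identical(t, "heading")) "markdown" else t
  }
  src_of <- function(cell) {
    s <- cell$source
    if (is.null(s)) s <- cell$input
    if (is.list(s)) s <- paste(unlist(s), collapse = "")
    if (is.null(s)) "" else s
  }
  types <- vapply(cells, type_of, character(1))
  list(
    cells_total = length(cells),
    code_cells = sum(types == "code"),
    markdown_cells = sum(types == "markdown"),
    raw_cells = sum(types == "raw"),
    empty_cells = sum(!nzchar(trimws(vapply(cells, src_of, character(1))))),
    cells_with_output = sum(vapply(cells, function(c) {
      identical(c$cell_type, "code") && length(c$outputs) > 0
    }, logical(1)))
  )
}

test_that("structure census equals an independent raw-document recount", {
  for (behavior in c("clean_identical", "exc_KeyError", "non_target_kernel",
                     "unknown_language")) {
    forged <- forge_notebook(behavior,
                             structure = list(code = 3L, markdown = 2L,
                                              raw = 1L, empty = 1L,
                                              title = paste("T", behavior)),
                             seed = 11L)
    path <- tempfile(fileext = ".ipynb")
    write_notebook(forged$doc, path)
    s <- profile_structure(read_notebook(path))
    oracle <- brute_force_recount(path)
    for (field in names(oracle)) {
      expect_identical(s[[field]], oracle[[field]],
                       label = paste(behavior, field))
    }
    expect_identical(s$cells_total, s$code_cells + s$markdown_cells + s$raw_cells)
  }
})

test_that("a whitespace-only cell counts as empty; execution counts are tracked", {
  nb <- h_notebook(list(
    h_cell("code", "print(1)", ec = 3L),
    h_cell("code", "   \n  "),
    h_cell("markdown", "# T"),
    h_cell("raw", "raw text")))
  s <- profile_structure(read_notebook(h_write_nb(nb)))
  expect_identical(s$cells_total, 4L)
  expect_identical(s$empty_cells, 1L)
  expect_identical(s$max_execution_count, 3)
  expect_true(s$has_execution_counts)
})

test_that("language falls back kernelspec -> language_info -> unknown", {
  no_meta <- h_notebook(list(h_cell("code", "x = 1")), kernel = NULL)
  s <- profile_structure(read_notebook(h_write_nb(no_meta)))
  expect_identical(s$language, "unknown")
  expect_true(is.na(s$language_version_full))

  versioned <- h_notebook(list(h_cell("code", "x = 1")), version = "3.7.12")
  s2 <- profile_structure(read_notebook(h_write_nb(versioned)))
  expect_identical(s2$language, "python")
  expect_identical(s2$language_version_full, "3.7.12")
  expect_identical(s2$major_version, 3L)
})

test_that("a zero-cell notebook has all-zero counts and no execution counts", {
  s <- profile_structure(read_notebook(h_write_nb(h_notebook(list()))))
  expect_identical(s$cells_total, 0L)
  expect_false(s$has_execution_counts)
  expect_true(is.na(s$max_execution_count))
})

test_that("v3 documents are upgraded on read: worksheets flattened, headings mapped", {
  v3 <- list(nbformat = 3L, nbformat_minor = 0L,
             metadata = setNames(list(), character(0)),
             worksheets = list(list(cells = list(
               list(cell_type = "heading", level = 2L, source = "Old title"),
               list(cell_type = "code", input = "print(9)", outputs = list(),
                    prompt_number = 4L)))))
  path <- tempfile(fileext = ".ipynb")
  writeLines(jsonlite::toJSON(v3, auto_unbox = TRUE, null = "null"), path)
  nb <- read_notebook(path)
  expect_identical(length(nb$cells), 2L)
  expect_identical(nb$cells[[1]]$cell_type, "markdown")
  expect_match(nb$cells[[1]]$source, "^## Old title")
  expect_identical(nb$cells[[2]]$source, "print(9)")
  s <- profile_structure(nb)
  expect_identical(s$code_cells, 1L)
  expect_identical(s$markdown_cells, 1L)
})

test_that("Markdown elements are detected by grammar", {
  nb <- h_notebook(list(
    h_cell("markdown", "# Title\n\nA paragraph of text."),
    h_cell("markdown", "- item one\n- item two\n\n```\ncode block\n```"),
    h_cell("markdown", "See [link](https://example.org) and ![img](x.png)"),
    h_cell("code", "pass")))
  md <- profile_markdown(read_notebook(h_write_nb(nb)))
  expect_setequal(md$elements_present,
                  c("header", "paragraph", "list", "code_block", "link", "image"))
  expect_gt(md$total_words, 0)
})

test_that("a notebook without Markdown reports zero words and undetected language", {
  nb <- h_notebook(list(h_cell("code", "x = 1")))
  md <- profile_markdown(read_notebook(h_write_nb(nb)))
  expect_identical(md$total_words, 0L)
  expect_identical(md$languages_detected, "undetected")
  expect_false(md$english_only)
})

test_that("a bilingual notebook is not english-only under a deterministic stub detector", {
  stub <- function(text) if (grepl("bonjour", text)) "fr" else "en"
  nb <- h_notebook(list(
    h_cell("markdown", "This text is in English."),
    h_cell("markdown", "bonjour tout le monde"),
    h_cell("code", "pass")))
  md <- profile_markdown(read_notebook(h_write_nb(nb)), lang_detector = stub)
  expect_setequal(md$languages_detected, c("en", "fr"))
  expect_false(md$english_only)

  english <- h_notebook(list(h_cell("markdown", "Only English here.")))
  md2 <- profile_markdown(read_notebook(h_write_nb(english)), lang_detector = stub)
  expect_true(md2$english_only)
})

test_that("the stopword detector separates clear English from clear French", {
  expect_identical(
    detect_language_stopwords(
      "the results of the analysis are shown in this figure and that table"),
    "en")
  expect_identical(
    detect_language_stopwords(
      "les figures dans la section montrent que nous avons pour une analyse"),
    "fr")
  expect_identical(detect_language_stopwords("x y"), "undetected")
})

test_that("name profiling flags Untitled, Copy, test, and portability", {
  p <- profile_name("Untitled3.ipynb")
  expect_true(p$is_untitled)
  expect_true(p$posix_portable)

  p2 <- profile_name("my analysis (copy).ipynb")
  expect_false(p2$posix_portable)
  expect_true(p2$contains_copy)

  p3 <- profile_name("a.ipynb")
  expect_identical(p3$title_length, 1L)

  p4 <- profile_name("test_pipeline.ipynb")
  expect_true(p4$contains_test)

  p5 <- profile_name("sub/dir/CON.ipynb")
  expect_true(p5$windows_disallowed)
  expect_identical(p5$title, "CON")
})

test_that("imports are split into external and local with directives stripped", {
  repo <- tempfile(); dir.create(file.path(repo, "pkgdir"), recursive = TRUE)
  writeLines("def f():\n    pass", file.path(repo, "utils.py"))
  writeLines("", file.path(repo, "pkgdir", "__init__.py"))
  nb <- h_notebook(list(
    h_cell("code", "import numpy as np\nimport pandas"),
    h_cell("code", "from utils import f\nimport pkgdir"),
    h_cell("code", "%load_ext autoreload\n!pip install something\nimport os"),
    h_cell("code", "from . import sibling")))
  imp <- profile_imports(read_notebook(h_write_nb(nb)), repo)
  expect_setequal(imp$modules_external, c("numpy", "pandas", "os"))
  expect_setequal(imp$modules_local, c("utils", "pkgdir", "."))
  expect_identical(imp$load_extensions, "autoreload")
  expect_true(imp$syntax_ok)
  expect_length(intersect(imp$modules_external, imp$modules_local), 0)
})

test_that("import multisets are invariant under cell reordering", {
  repo <- tempfile(); dir.create(repo)
  cells <- list(h_cell("code", "import numpy"),
                h_cell("code", "import scipy\nimport numpy"),
                h_cell("code", "import pandas"))
  fwd <- profile_imports(read_notebook(h_write_nb(h_notebook(cells))), repo)
  rev <- profile_imports(read_notebook(h_write_nb(h_notebook(base::rev(cells)))), repo)
  expect_identical(sort(fwd$modules_external), sort(rev$modules_external))
})

test_that("a syntax failure in one cell is best-effort, not fatal", {
  repo <- tempfile(); dir.create(repo)
  nb <- h_notebook(list(
    h_cell("code", "import numpy"),
    h_cell("code", "def broken(:\n    pass"),
    h_cell("code", "import json\ndef ok():\n    pass\nclass C:\n    pass")))
  imp <- profile_imports(read_notebook(h_write_nb(nb)), repo)
  expect_false(imp$syntax_ok)
  expect_setequal(imp$modules_external, c("numpy", "json"))
  expect_identical(imp$functions_defined, 1L)
  expect_identical(imp$classes_defined, 1L)
})

test_that("planted style violations yield exactly the planted codes", {
  nb <- h_notebook(list(
    h_cell("code", "x=1"),                       # E225
    h_cell("code", "f(a,b)"),                    # E231
    h_cell("code", "x = 1\nimport os"),          # E402
    h_cell("code", "print(1);"),                 # E703
    h_cell("code", "y = f(a, b) + 1"),           # clean
    h_cell("code", "")))                         # empty
  findings <- profile_style(read_notebook(h_write_nb(nb)))
  by_cell <- split(findings$code, findings$cell_index)
  expect_identical(by_cell[["0"]], "E225")
  expect_identical(by_cell[["1"]], "E231")
  expect_identical(by_cell[["2"]], "E402")
  expect_identical(by_cell[["3"]], "E703")
  expect_false("4" %in% names(by_cell))
  expect_false("5" %in% names(by_cell))
})

test_that("style findings never point inside string literals or magics", {
  nb <- h_notebook(list(
    h_cell("code", "s = 'a,b=c;'"),
    h_cell("code", "%matplotlib inline"),
    h_cell("code", "u = \"x=1\"")))
  findings <- profile_style(read_notebook(h_write_nb(nb)))
  expect_identical(nrow(findings), 0L)
})

test_that("comment styling codes are detected", {
  f <- style_engine_default("#bad block comment\nx = 1  ## bad inline")
  expect_setequal(f$code, c("E265", "E262"))
})
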
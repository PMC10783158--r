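# Synthetic-corpus forge: seeded, fully labelled offline corpora — JATS
# articles with planted link dialects, repository trees with declaration
# files, a local package index, and notebooks engineered to land in every
# pipeline outcome. The manifest is the ground truth for round-trip tests.

BEHAVIOR_LABELS <- c("clean_identical", "clean_different",
                     "exc_ModuleNotFoundError", "exc_FileNotFoundError",
                     "exc_ImportError", "exc_NameError", "exc_IOError",
                     "exc_AttributeError", "exc_ValueError", "exc_TypeError",
                     "exc_KeyError", "timeout", "non_target_kernel",
                     "unknown_language", "install_fail")

# the statement whose execution deterministically raises each exception class
EXC_SNIPPETS <- c(
  exc_ModuleNotFoundError = "import nonexistent_module_zqx13",
  exc_FileNotFoundError = "open('definitely_missing_file_zqx13.txt')",
  exc_ImportError = "from os import nonexistent_name_zqx13",
  exc_NameError = "print(undefined_variable_zqx13)",
  exc_IOError = "raise IOError('synthetic io failure')",
  exc_AttributeError = "''.nonexistent_attribute_zqx13()",
  exc_ValueError = "int('not-a-number')",
  exc_TypeError = "len(1)",
  exc_KeyError = "{}['missing_key_zqx13']"
)

# raised name as written vs the class name a modern interpreter reports
EXC_EXPECTED_ENAME <- c(
  exc_ModuleNotFoundError = "ModuleNotFoundError",
  exc_FileNotFoundError = "FileNotFoundError",
  exc_ImportError = "ImportError",
  exc_NameError = "NameError",
  exc_IOError = "OSError",
  exc_AttributeError = "AttributeError",
  exc_ValueError = "ValueError",
  exc_TypeError = "TypeError",
  exc_KeyError = "KeyError"
)

behavior_expected_outcome <- function(label) {
  if (label %in% names(EXC_EXPECTED_ENAME)) return("exception")
  switch(label,
         clean_identical = "finished_identical",
         clean_different = "finished_different",
         timeout = "timeout",
         non_target_kernel = "not_target_language",
         unknown_language = "not_target_language",
         install_fail = "install_failed",
         stop("unknown behavior label: ", label))
}

FORGE_SENTENCES <- c(
  "This notebook documents the analysis of the simulated assay data.",
  "The results in this section are derived from the counts loaded above.",
  "We summarize the distribution of the measurements for each condition.",
  "The following cells reproduce the figures reported in the manuscript.",
  "Quality control was performed before fitting the model to the data."
)

forge_markdown_cells <- function(n, title) {
  if (n == 0L) return(list())
  cells <- list(nb_markdown_cell(paste0("# ", title, "\n\n", FORGE_SENTENCES[1])))
  i <- 2L
  while (length(cells) < n) {
    body <- FORGE_SENTENCES[((i - 1L) %% length(FORGE_SENTENCES)) + 1L]
    cells[[length(cells) + 1L]] <- nb_markdown_cell(
      paste0("## Step ", i - 1L, "\n\n", body))
    i <- i + 1L
  }
  cells
}

# deterministic print cell; its stdout is predictable so stored outputs for
# never-executed fixtures can be planted exactly. The second cell of every
# notebook is written sloppily (tight '=', tight commas, trailing semicolon)
# so the corpus carries the frequent style findings; output is unchanged.
forge_print_cell <- function(i, a, b, with_output = TRUE, count = NULL) {
  value <- a * i + b
  src <- if (i == 2L) {
    sprintf("v%d=%d; print('block',%d,'->',v%d);", i, value, i, i)
  } else {
    sprintf("print('block', %d, '->', %d)", i, value)
  }
  outputs <- if (with_output) {
    list(nb_stream_output(sprintf("block %d -> %d\n", i, value)))
  } else {
    list()
  }
  nb_code_cell(src, outputs = outputs, execution_count = count)
}

#' Forge a notebook with an engineered runtime behavior
#'
#' Builds a notebook document whose re-execution lands in a known pipeline
#' outcome: clean deterministic, clean but drawing unseeded entropy, a
#' designated cell raising exactly one exception class, a sleep past the
#' timeout, a non-Python kernel, missing language metadata, or clean code in
#' a repository whose declared dependencies cannot be installed.
#'
#' Notebooks whose stored outputs must match a fresh run (`clean_identical`)
#' are executed once at forge time by [forge_repository()]; fixtures that are
#' never (or incompletely) executed carry planted outputs matching their
#' deterministic prints.
#'
#' @param behavior One of the behavior labels in `BEHAVIOR_LABELS`.
#' @param structure List with `code`, `markdown`, `raw`, `empty` cell counts
#'   and `title`.
#' @param seed Integer seed; the document is a pure function of
#'   `(behavior, structure, seed)`.
#' @param params Behavior parameters (e.g. `sleep` seconds for `timeout`,
#'   `fail_at` code-cell ordinal for exceptions).
#' @return A list with `doc` (the notebook), `behavior`,
#'   `expected_outcome`, `expected_exception`, `needs_forge_execution`.
#' @export
forge_notebook <- function(behavior, structure = list(), seed = 1L,
                           params = list()) {
  stopifnot(behavior %in% BEHAVIOR_LABELS)
  spec <- utils::modifyList(
    list(code = 3L, markdown = 2L, raw = 0L, empty = 0L, title = "Forged analysis"),
    structure)
  set.seed(derive_seed(seed, paste0(behavior, spec$title)))
  a <- sample(2:9, 1); b <- sample(10:99, 1)

  md <- forge_markdown_cells(spec$markdown, spec$title)
  code <- list()
  n_code <- max(spec$code, 1L)

  if (behavior %in% names(EXC_SNIPPETS)) {
    fail_at <- params$fail_at %||% n_code
    stopifnot(fail_at >= 1L, fail_at <= n_code)
    for (i in seq_len(n_code)) {
      if (i < fail_at) {
        code[[i]] <- forge_print_cell(i, a, b, with_output = TRUE, count = i)
      } else if (i == fail_at) {
        code[[i]] <- nb_code_cell(unname(EXC_SNIPPETS[behavior]),
                                  outputs = list(), execution_count = i)
      } else {
        code[[i]] <- forge_print_cell(i, a, b, with_output = FALSE, count = NULL)
      }
    }
  } else if (identical(behavior, "clean_different")) {
    for (i in seq_len(n_code - 1L)) {
      code[[i]] <- forge_print_cell(i, a, b, with_output = TRUE, count = i)
    }
    # stored output planted with a draw no fresh run will reproduce
    planted <- sprintf("draw: 0.%09d\n", sample.int(999999999L, 1))
    code[[n_code]] <- nb_code_cell(
      "import random\nprint('draw:', random.random())",
      outputs = list(nb_stream_output(planted)), execution_count = n_code)
  } else if (identical(behavior, "timeout")) {
    sleep <- params$sleep %||% 25
    for (i in seq_len(n_code - 1L)) {
      code[[i]] <- forge_print_cell(i, a, b, with_output = TRUE, count = i)
    }
    code[[n_code]] <- nb_code_cell(
      sprintf("import time\ntime.sleep(%s)\nprint('woke up')", format(sleep)),
      outputs = list(), execution_count = n_code)
  } else if (identical(behavior, "non_target_kernel")) {
    lang <- params$language %||% "R"
    for (i in seq_len(n_code)) {
      code[[i]] <- nb_code_cell(sprintf("print('foreign cell %d')", i),
                                outputs = list(), execution_count = i)
    }
  } else {
    # clean_identical, unknown_language, install_fail: deterministic prints
    for (i in seq_len(n_code)) {
      code[[i]] <- forge_print_cell(i, a, b, with_output = TRUE, count = i)
    }
    if (!is.null(params$local_import)) {
      code[[1L]] <- nb_code_cell(
        paste0("from ", params$local_import, " import helper\n",
               "print('helper ->', helper(3))"),
        outputs = list(), execution_count = 1L)
    }
  }

  cells <- list()
  k <- 1L
  for (i in seq_along(code)) {
    if (k <= length(md)) { cells[[length(cells) + 1L]] <- md[[k]]; k <- k + 1L }
    cells[[length(cells) + 1L]] <- code[[i]]
  }
  while (k <= length(md)) { cells[[length(cells) + 1L]] <- md[[k]]; k <- k + 1L }
  for (i in seq_len(spec$empty)) {
    cells[[length(cells) + 1L]] <- nb_code_cell("   ", outputs = list())
  }
  for (i in seq_len(spec$raw)) {
    cells[[length(cells) + 1L]] <- nb_raw_cell("raw block, never evaluated")
  }

  doc <- if (identical(behavior, "non_target_kernel")) {
    lang <- params$language %||% "R"
    new_notebook(cells, kernel_name = if (identical(lang, "R")) "ir" else "julia-1.9",
                 language = lang,
                 language_version = if (identical(lang, "R")) "4.3.1" else "1.9.0")
  } else if (identical(behavior, "unknown_language")) {
    new_notebook(cells, kernel_name = NULL, language = NULL, language_version = NULL)
  } else {
    new_notebook(cells, kernel_name = "python3", language = "python",
                 language_version = params$python_version %||% "3.11")
  }

  list(doc = doc, behavior = behavior,
       expected_outcome = behavior_expected_outcome(behavior),
       expected_exception = unname(EXC_EXPECTED_ENAME[behavior]) %||% NA_character_,
       needs_forge_execution = identical(behavior, "clean_identical"),
       cells_total = length(cells),
       code_cells = length(code) + spec$empty,
       markdown_cells = length(md),
       raw_cells = spec$raw)
}

#' Publish the local package index
#'
#' Writes one tiny pure-source distribution (`forgepkg`) into an index
#' directory so that "declared and installable" is testable without network
#' access: the local-index environment backend resolves requirement names
#' against this directory.
#'
#' @param index_dir Index directory (created).
#' @return `index_dir`, invisibly.
#' @export
publish_local_index <- function(index_dir) {
  pkg_dir <- file.path(index_dir, "forgepkg", "forgepkg")
  dir.create(pkg_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("def helper(x):", "    return 2 * x + 1"),
             file.path(pkg_dir, "__init__.py"))
  writeLines(c("from setuptools import setup",
               "setup(name='forgepkg', version='0.1', packages=['forgepkg'])"),
             file.path(index_dir, "forgepkg", "setup.py"))
  invisible(index_dir)
}

#' Forge one repository working tree
#'
#' Writes the declared dependency files and every requested notebook;
#' `clean_identical` notebooks are then executed once in place so their
#' stored outputs come from a real run. Repositories marked not installable
#' declare a guaranteed-unresolvable requirement; installable ones declare
#' only the locally published package.
#'
#' @param spec List with `owner`, `name`, `declarations` (subset of
#'   `c("requirements", "setup", "pipfile")`), `installable`, and `notebooks`
#'   (list of `list(path, behavior, structure, params)`).
#' @param out_dir Directory under which `{owner}/{name}` is created.
#' @param seed Integer seed.
#' @param timeout_sleep Sleep used by timeout fixtures (seconds).
#' @return A data.frame manifest, one row per notebook.
#' @export
forge_repository <- function(spec, out_dir, seed = 1L, timeout_sleep = 25) {
  root <- file.path(out_dir, spec$owner, spec$name)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  requirement <- if (isTRUE(spec$installable)) "forgepkg>=0.1" else
    "no-such-package-zqx13==9.9"
  if ("requirements" %in% spec$declarations) {
    writeLines(c("# declared dependencies", requirement),
               file.path(root, "requirements.txt"))
  }
  if ("setup" %in% spec$declarations) {
    writeLines(c("from setuptools import setup",
                 sprintf("setup(name='%s', version='0.1', install_requires=['%s'])",
                         spec$name, requirement)),
               file.path(root, "setup.py"))
  }
  if ("pipfile" %in% spec$declarations) {
    writeLines(c("[[source]]", "url = \"https://example.invalid/simple\"", "",
                 "[packages]",
                 sprintf("%s = \"*\"", sub("[<>=!~].*$", "", requirement))),
               file.path(root, "Pipfile"))
  }
  writeLines(paste0("# ", spec$name, "\n\nForged fixture repository."),
             file.path(root, "README.md"))
  for (extra in spec$extra_files %||% list()) {
    path <- file.path(root, extra$path)
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    writeLines(extra$lines, path)
  }

  rows <- list()
  canonical <- paste0("https://github.com/", spec$owner, "/", spec$name)
  for (nbspec in spec$notebooks) {
    path <- file.path(root, nbspec$path)
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    if (identical(nbspec$behavior, "raw_invalid_json")) {
      writeLines("this is not a notebook", path)
      rows[[length(rows) + 1L]] <- data.frame(
        repo_url = canonical, relative_path = nbspec$path,
        behavior = "raw_invalid_json", expected_outcome = "no_declared_pipeline_entry",
        expected_exception = NA_character_, cells_total = NA_integer_,
        code_cells = NA_integer_, markdown_cells = NA_integer_,
        raw_cells = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    params <- nbspec$params %||% list()
    if (identical(nbspec$behavior, "timeout")) params$sleep <- timeout_sleep
    forged <- forge_notebook(nbspec$behavior, nbspec$structure %||% list(),
                             seed = derive_seed(seed, nbspec$path),
                             params = params)
    if (isTRUE(nbspec$v3)) {
      write_v3_notebook(forged$doc, path)
    } else {
      write_notebook(forged$doc, path)
      if (forged$needs_forge_execution) {
        embed_forge_outputs(path)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      repo_url = canonical, relative_path = nbspec$path,
      behavior = forged$behavior, expected_outcome = forged$expected_outcome,
      expected_exception = forged$expected_exception,
      cells_total = forged$cells_total, code_cells = forged$code_cells,
      markdown_cells = forged$markdown_cells, raw_cells = forged$raw_cells,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# execute a freshly forged clean notebook once and embed the produced outputs
embed_forge_outputs <- function(path) {
  handle <- list(python = nbaudit_python())
  trace <- execute_notebook(path, handle, timeout = 60)
  if (!isTRUE(trace$completed)) {
    stop("forge-time execution of ", path, " failed: ",
         trace$first_exception_type %||% "timeout", call. = FALSE)
  }
  executed <- read_notebook(trace$executed_path)
  doc <- read_notebook(path)
  stopifnot(length(doc$cells) == length(executed$cells))
  for (i in seq_along(doc$cells)) {
    if (!identical(doc$cells[[i]]$cell_type, "code")) next
    doc$cells[[i]]$outputs <- executed$cells[[i]]$outputs %||% list()
    doc$cells[[i]]$execution_count <- executed$cells[[i]]$execution_count
  }
  write_notebook(doc, path)
  unlink(trace$executed_path)
  invisible(path)
}

# serialize a document in the legacy v3 layout (worksheets, input,
# prompt_number) to exercise the upgrade path
write_v3_notebook <- function(doc, path) {
  cells <- lapply(doc$cells, function(cell) {
    if (identical(cell$cell_type, "code")) {
      list(cell_type = "code", input = cell$source, language = "python",
           outputs = list(), prompt_number = cell$execution_count)
    } else {
      list(cell_type = cell$cell_type, source = cell$source)
    }
  })
  v3 <- list(nbformat = 3L, nbformat_minor = 0L,
             metadata = empty_json_object(),
             worksheets = list(list(cells = cells)))
  json <- jsonlite::toJSON(v3, auto_unbox = TRUE, null = "null", pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

# --- JATS forging ---------------------------------------------------------

render_link_dialect <- function(dialect, owner, repo) {
  base <- paste0("https://github.com/", owner, "/", repo)
  switch(dialect,
    plain = base,
    blob_path = paste0(base, "/blob/main/notebooks/analysis01.ipynb"),
    tree_path = paste0(base, "/tree/main/src"),
    nbviewer = paste0("https://nbviewer.jupyter.org/github/", owner, "/", repo,
                      "/blob/main/Index.ipynb"),
    raw_host = paste0("https://raw.githubusercontent.com/", owner, "/", repo,
                      "/main/requirements.txt"),
    git_suffix = paste0(base, ".git"),
    schemeless = paste0("github.com/", owner, "/", repo),
    trailing_slash = paste0(base, "/"),
    fragment = paste0(base, "#readme"),
    owner_only = paste0("https://github.com/", owner),
    pages_site = paste0("https://", owner, ".github.io/", repo),
    gist = paste0("https://gist.github.com/", owner, "/abc123def456"),
    stop("unknown link dialect: ", dialect)
  )
}

dialect_expectation <- function(dialect, owner, repo) {
  rejection <- c(owner_only = "owner_only", pages_site = "pages_site",
                 gist = "non_repo_host")
  if (dialect %in% names(rejection)) {
    list(canonical = NA_character_, reason = unname(rejection[dialect]))
  } else {
    list(canonical = paste0("https://github.com/", owner, "/", repo),
         reason = NA_character_)
  }
}

#' Forge one JATS article
#'
#' Builds a valid JATS skeleton with the requested repository links planted
#' in the requested sections (`abstract`, `body`, `back`) and encodings
#' (`ext-link` href or plain text). Metadata fields are drawn
#' deterministically from the spec; omitted fields stay absent.
#'
#' @param spec List with `pmc_id` and optionally `title`, `journal` (list
#'   `issn`, `title`, `nlm`), `publisher`, `article_type`, dates, `license`,
#'   `keywords`, `mesh`, `authors`, and `links` (list of
#'   `list(dialect, owner, repo, section, encoding)`).
#' @param out_dir Directory for the XML file.
#' @param seed Integer seed.
#' @return A list with `path`, the article manifest row, and the planted
#'   link expectations (data.frame).
#' @export
forge_article <- function(spec, out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  doc <- xml2::xml_new_root("article",
                            "xmlns:xlink" = "http://www.w3.org/1999/xlink")
  if (!is.null(spec$article_type)) {
    xml2::xml_set_attr(doc, "article-type", spec$article_type)
  }
  front <- xml2::xml_add_child(doc, "front")
  jm <- xml2::xml_add_child(front, "journal-meta")
  if (!is.null(spec$journal)) {
    if (!is.null(spec$journal$nlm)) {
      id <- xml2::xml_add_child(jm, "journal-id", spec$journal$nlm)
      xml2::xml_set_attr(id, "journal-id-type", "nlm-ta")
    }
    tg <- xml2::xml_add_child(jm, "journal-title-group")
    xml2::xml_add_child(tg, "journal-title", spec$journal$title)
    if (!is.null(spec$journal$issn)) {
      xml2::xml_add_child(jm, "issn", spec$journal$issn)
    }
    if (!is.null(spec$publisher)) {
      pub <- xml2::xml_add_child(jm, "publisher")
      xml2::xml_add_child(pub, "publisher-name", spec$publisher)
    }
  }
  am <- xml2::xml_add_child(front, "article-meta")
  add_id <- function(type, value) {
    if (is.null(value)) return()
    id <- xml2::xml_add_child(am, "article-id", value)
    xml2::xml_set_attr(id, "pub-id-type", type)
  }
  add_id("pmc", spec$pmc_id)
  add_id("pmid", spec$pubmed_id)
  add_id("doi", spec$doi)
  if (!is.null(spec$mesh)) {
    cats <- xml2::xml_add_child(am, "article-categories")
    grp <- xml2::xml_add_child(cats, "subj-group")
    xml2::xml_set_attr(grp, "subj-group-type", "mesh")
    for (term in spec$mesh) xml2::xml_add_child(grp, "subject", term)
  }
  tg <- xml2::xml_add_child(am, "title-group")
  xml2::xml_add_child(tg, "article-title", spec$title %||% "Untitled study")
  if (!is.null(spec$authors)) {
    cg <- xml2::xml_add_child(am, "contrib-group")
    for (author in spec$authors) {
      contrib <- xml2::xml_add_child(cg, "contrib")
      xml2::xml_set_attr(contrib, "contrib-type", "author")
      if (!is.null(author$orcid)) {
        cid <- xml2::xml_add_child(contrib, "contrib-id", author$orcid)
        xml2::xml_set_attr(cid, "contrib-id-type", "orcid")
      }
      nm <- xml2::xml_add_child(contrib, "name")
      xml2::xml_add_child(nm, "surname", author$surname)
      xml2::xml_add_child(nm, "given-names", author$given)
      if (!is.null(author$email)) xml2::xml_add_child(contrib, "email", author$email)
    }
  }
  if (!is.null(spec$date_received) || !is.null(spec$date_accepted)) {
    hist <- xml2::xml_add_child(am, "history")
    add_date <- function(type, value) {
      if (is.null(value)) return()
      d <- as.Date(value)
      node <- xml2::xml_add_child(hist, "date")
      xml2::xml_set_attr(node, "date-type", type)
      xml2::xml_add_child(node, "day", format(d, "%d"))
      xml2::xml_add_child(node, "month", format(d, "%m"))
      xml2::xml_add_child(node, "year", format(d, "%Y"))
    }
    add_date("received", spec$date_received)
    add_date("accepted", spec$date_accepted)
  }
  if (!is.null(spec$date_published)) {
    d <- as.Date(spec$date_published)
    node <- xml2::xml_add_child(am, "pub-date")
    xml2::xml_set_attr(node, "pub-type", "epub")
    xml2::xml_add_child(node, "day", format(d, "%d"))
    xml2::xml_add_child(node, "month", format(d, "%m"))
    xml2::xml_add_child(node, "year", format(d, "%Y"))
  }
  if (!is.null(spec$license)) {
    perms <- xml2::xml_add_child(am, "permissions")
    xml2::xml_add_child(perms, "copyright-statement",
                        paste0("(c) ", spec$copyright %||% "The Authors"))
    lic <- xml2::xml_add_child(perms, "license")
    xml2::xml_add_child(lic, "license-p", spec$license)
  }
  if (!is.null(spec$keywords)) {
    kg <- xml2::xml_add_child(am, "kwd-group")
    for (kw in spec$keywords) xml2::xml_add_child(kg, "kwd", kw)
  }

  links <- spec$links %||% list()
  sections <- list(abstract = NULL, body = NULL, back = NULL)
  abstract <- xml2::xml_add_child(am, "abstract")
  xml2::xml_add_child(abstract, "p", "Forged abstract describing the study.")
  sections$abstract <- abstract
  body <- xml2::xml_add_child(doc, "body")
  sec <- xml2::xml_add_child(body, "sec")
  xml2::xml_add_child(sec, "title", "Methods")
  xml2::xml_add_child(sec, "p", "Analyses were performed in notebooks.")
  sections$body <- sec
  back <- xml2::xml_add_child(doc, "back")
  da <- xml2::xml_add_child(back, "sec")
  xml2::xml_set_attr(da, "sec-type", "data-availability")
  xml2::xml_add_child(da, "title", "Data availability")
  xml2::xml_add_child(da, "p", "Code supporting this study is available online.")
  sections$back <- da

  expectations <- list()
  for (link in links) {
    raw <- render_link_dialect(link$dialect, link$owner, link$repo)
    target <- sections[[link$section %||% "body"]]
    if (identical(link$encoding %||% "ext-link", "ext-link")) {
      p <- xml2::xml_add_child(target, "p", "Code is available from ")
      el <- xml2::xml_add_child(p, "ext-link", "the project repository")
      xml2::xml_set_attr(el, "ext-link-type", "uri")
      xml2::xml_set_attr(el, "xlink:href", raw)
    } else {
      xml2::xml_add_child(target, "p", paste0("See ", raw, " for the code."))
    }
    exp <- dialect_expectation(link$dialect, link$owner, link$repo)
    expectations[[length(expectations) + 1L]] <- data.frame(
      pmc_id = spec$pmc_id, raw = raw, dialect = link$dialect,
      section = link$section %||% "body",
      expected_canonical = exp$canonical, expected_reason = exp$reason,
      stringsAsFactors = FALSE)
  }
  path <- file.path(out_dir, paste0(spec$pmc_id, ".xml"))
  xml2::write_xml(doc, path)
  list(path = path,
       article = data.frame(pmc_id = spec$pmc_id,
                            title = spec$title %||% "Untitled study",
                            journal_issn = spec$journal$issn %||% NA_character_,
                            journal_title = spec$journal$title %||% NA_character_,
                            n_links = length(links), stringsAsFactors = FALSE),
       links = if (length(expectations)) do.call(rbind, expectations) else
         data.frame(pmc_id = character(0), raw = character(0),
                    dialect = character(0), section = character(0),
                    expected_canonical = character(0),
                    expected_reason = character(0), stringsAsFactors = FALSE))
}
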
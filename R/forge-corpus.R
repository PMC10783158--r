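# Default corpus configuration and the whole-corpus forge.

#' Default forge configuration
#'
#' The desk-scale study conditions: 10 linked repositories (one of them
#' unavailable), 39 notebook files covering all 15 behavior labels at least
#' twice, 8 articles planting every recognized link dialect plus the
#' rejected forms, and an execution policy pairing a 5-second timeout with
#' timeout fixtures sleeping five times that.
#'
#' @param timeout_sleep Seconds slept by timeout fixtures.
#' @param execution_timeout Matching per-notebook timeout for pipeline runs.
#' @return A config list for [forge_corpus()].
#' @export
default_forge_config <- function(timeout_sleep = 25, execution_timeout = 5) {
  repos <- list(
    list(owner = "lab-alpha", name = "clean-suite",
         declarations = "requirements", installable = TRUE,
         extra_files = list(list(path = "notebooks/forgeutils.py",
                                 lines = c("def helper(x):",
                                           "    return 10 * x + 7"))),
         notebooks = list(
           list(path = "notebooks/analysis01.ipynb", behavior = "clean_identical",
                structure = list(code = 4L, markdown = 3L, raw = 1L,
                                 title = "Primary analysis"),
                params = list(local_import = "forgeutils")),
           list(path = "Index.ipynb", behavior = "clean_identical",
                structure = list(code = 3L, markdown = 2L, title = "Index")),
           list(path = "Untitled2.ipynb", behavior = "clean_identical",
                structure = list(code = 2L, markdown = 0L, title = "Scratch")),
           list(path = "random draw (Copy).ipynb", behavior = "clean_different",
                structure = list(code = 3L, markdown = 1L, title = "Random draw")),
           list(path = "figs/make_figures.ipynb", behavior = "clean_different",
                structure = list(code = 2L, markdown = 2L, title = "Figures")))),
    list(owner = "lab-alpha", name = "mixed-decls",
         declarations = c("requirements", "setup"), installable = TRUE,
         notebooks = list(
           list(path = "fnf_a.ipynb", behavior = "exc_FileNotFoundError",
                structure = list(code = 3L, markdown = 1L, title = "Reader A")),
           list(path = "deep/fnf_b.ipynb", behavior = "exc_FileNotFoundError",
                structure = list(code = 2L, markdown = 1L, title = "Reader B"),
                params = list(fail_at = 1L)),
           list(path = "io_a.ipynb", behavior = "exc_IOError",
                structure = list(code = 3L, markdown = 2L, title = "Writer A")),
           list(path = "io_b.ipynb", behavior = "exc_IOError",
                structure = list(code = 2L, markdown = 0L, title = "Writer B")))),
    list(owner = "lab-beta", name = "import-errors",
         declarations = "setup", installable = TRUE,
         notebooks = list(
           list(path = "mnfe_a.ipynb", behavior = "exc_ModuleNotFoundError",
                structure = list(code = 3L, markdown = 1L, title = "Modules A"),
                params = list(fail_at = 1L)),
           list(path = "mnfe_b.ipynb", behavior = "exc_ModuleNotFoundError",
                structure = list(code = 2L, markdown = 1L, title = "Modules B")),
           list(path = "mnfe_c.ipynb", behavior = "exc_ModuleNotFoundError",
                structure = list(code = 4L, markdown = 2L, title = "Modules C")),
           list(path = "imp_a.ipynb", behavior = "exc_ImportError",
                structure = list(code = 3L, markdown = 1L, title = "Imports A")),
           list(path = "imp_b.ipynb", behavior = "exc_ImportError",
                structure = list(code = 2L, markdown = 2L, title = "Imports B")),
           list(path = "name_a.ipynb", behavior = "exc_NameError",
                structure = list(code = 3L, markdown = 1L, title = "Names A")),
           list(path = "name_b.ipynb", behavior = "exc_NameError",
                structure = list(code = 2L, markdown = 0L, title = "Names B")))),
    list(owner = "lab-beta", name = "value-errors",
         declarations = "pipfile", installable = TRUE,
         notebooks = list(
           list(path = "val_a.ipynb", behavior = "exc_ValueError",
                structure = list(code = 3L, markdown = 1L, title = "Values A")),
           list(path = "val_b.ipynb", behavior = "exc_ValueError",
                structure = list(code = 2L, markdown = 1L, title = "Values B")),
           list(path = "type_a.ipynb", behavior = "exc_TypeError",
                structure = list(code = 3L, markdown = 1L, title = "Types A")),
           list(path = "type_b.ipynb", behavior = "exc_TypeError",
                structure = list(code = 2L, markdown = 2L, title = "Types B")),
           list(path = "key_a.ipynb", behavior = "exc_KeyError",
                structure = list(code = 3L, markdown = 1L, title = "Keys A")),
           list(path = "key_b.ipynb", behavior = "exc_KeyError",
                structure = list(code = 2L, markdown = 0L, title = "Keys B")),
           list(path = "key_c.ipynb", behavior = "exc_KeyError",
                structure = list(code = 4L, markdown = 2L, title = "Keys C"),
                params = list(fail_at = 2L)))),
    list(owner = "lab-gamma", name = "attr-errors",
         declarations = character(0), installable = TRUE,
         notebooks = list(
           list(path = "attr_a.ipynb", behavior = "exc_AttributeError",
                structure = list(code = 3L, markdown = 1L, title = "Attributes A")),
           list(path = "attr_b.ipynb", behavior = "exc_AttributeError",
                structure = list(code = 2L, markdown = 1L, title = "Attributes B")),
           list(path = "smoke.ipynb", behavior = "clean_identical",
                structure = list(code = 2L, markdown = 1L, empty = 1L,
                                 title = "Smoke check")))),
    list(owner = "lab-gamma", name = "slow-sims",
         declarations = character(0), installable = TRUE,
         notebooks = list(
           list(path = "sim_long.ipynb", behavior = "timeout",
                structure = list(code = 3L, markdown = 1L, title = "Long simulation")),
           list(path = "sim_longer.ipynb", behavior = "timeout",
                structure = list(code = 2L, markdown = 1L, title = "Longer simulation")))),
    list(owner = "lab-delta", name = "foreign-kernels",
         declarations = character(0), installable = TRUE,
         notebooks = list(
           list(path = "r_analysis.ipynb", behavior = "non_target_kernel",
                structure = list(code = 3L, markdown = 1L, title = "R analysis"),
                params = list(language = "R")),
           list(path = "r_plots.ipynb", behavior = "non_target_kernel",
                structure = list(code = 2L, markdown = 1L, title = "R plots"),
                params = list(language = "R")),
           list(path = "julia_model.ipynb", behavior = "non_target_kernel",
                structure = list(code = 2L, markdown = 1L, title = "Julia model"),
                params = list(language = "julia")),
           list(path = "no_meta.ipynb", behavior = "unknown_language",
                structure = list(code = 2L, markdown = 1L, title = "No metadata")),
           list(path = "legacy_nb.ipynb", behavior = "unknown_language",
                structure = list(code = 2L, markdown = 1L, title = "Legacy"),
                v3 = TRUE))),
    list(owner = "lab-delta", name = "broken-reqs",
         declarations = "requirements", installable = FALSE,
         notebooks = list(
           list(path = "blocked_a.ipynb", behavior = "install_fail",
                structure = list(code = 3L, markdown = 1L, title = "Blocked A")),
           list(path = "blocked_b.ipynb", behavior = "install_fail",
                structure = list(code = 2L, markdown = 1L, title = "Blocked B")),
           list(path = "sub/blocked_c.ipynb", behavior = "install_fail",
                structure = list(code = 2L, markdown = 0L, title = "Blocked C")))),
    list(owner = "lab-epsilon", name = "odds-and-ends",
         declarations = "requirements", installable = TRUE,
         extra_files = list(list(
           # editor checkpoint copy: present on disk, excluded from harvest
           path = ".ipynb_checkpoints/tidy_run-checkpoint.ipynb",
           lines = '{"nbformat": 4, "nbformat_minor": 5, "metadata": {}, "cells": []}')),
         notebooks = list(
           list(path = "tidy_run.ipynb", behavior = "clean_identical",
                structure = list(code = 3L, markdown = 2L, title = "Tidy run")),
           list(path = "broken.ipynb", behavior = "raw_invalid_json")))
  )
  journals <- list(
    jA = list(issn = "1111-2222", title = "Journal of Forged Biology", nlm = "J Forg Biol"),
    jB = list(issn = "3333-4444", title = "Computational Fixtures", nlm = "Comput Fixt"),
    jC = list(title = "Synthetic Data Reports")
  )
  articles <- list(
    list(pmc_id = "PMC900001", title = "Clean analyses of forged assays",
         journal = journals$jA, publisher = "Forge Press",
         article_type = "research-article",
         pubmed_id = "33900001", doi = "10.1000/forge.900001",
         date_received = "2021-02-01", date_accepted = "2021-05-10",
         date_published = "2021-06-15",
         license = "Creative Commons Attribution 4.0",
         keywords = c("notebooks", "reproducibility"),
         mesh = c("Genomics", "Machine Learning"),
         authors = list(list(surname = "Alpha", given = "Ada",
                             orcid = "0000-0001-0000-0001"),
                        list(surname = "Beta", given = "Ben")),
         links = list(
           list(dialect = "plain", owner = "lab-alpha", repo = "clean-suite",
                section = "abstract", encoding = "ext-link"),
           list(dialect = "plain", owner = "lab-alpha", repo = "clean-suite",
                section = "back", encoding = "text"),
           list(dialect = "blob_path", owner = "lab-alpha", repo = "mixed-decls",
                section = "body", encoding = "text"))),
    list(pmc_id = "PMC900002", title = "Import failures in the wild",
         journal = journals$jA, publisher = "Forge Press",
         article_type = "research-article",
         date_published = "2022-03-02",
         mesh = c("Computational Biology", "Genomics"),
         authors = list(list(surname = "Gamma", given = "Gil")),
         links = list(
           list(dialect = "nbviewer", owner = "lab-beta", repo = "import-errors",
                section = "body", encoding = "ext-link"),
           list(dialect = "owner_only", owner = "lab-beta", repo = "import-errors",
                section = "body", encoding = "text"))),
    list(pmc_id = "PMC900003", title = "Value errors and attributes",
         journal = journals$jB, article_type = "software",
         date_published = "2022-07-21",
         mesh = c("Neoplasms"),
         links = list(
           list(dialect = "tree_path", owner = "lab-beta", repo = "value-errors",
                section = "body", encoding = "text"),
           list(dialect = "git_suffix", owner = "lab-gamma", repo = "attr-errors",
                section = "back", encoding = "ext-link"),
           list(dialect = "pages_site", owner = "lab-gamma", repo = "attr-errors",
                section = "body", encoding = "text"))),
    list(pmc_id = "PMC900004", title = "Slow simulations, foreign kernels",
         journal = journals$jB, article_type = "research-article",
         date_published = "2023-01-11",
         mesh = c("Machine Learning", "Information Science"),
         links = list(
           list(dialect = "raw_host", owner = "lab-gamma", repo = "slow-sims",
                section = "body", encoding = "text"),
           list(dialect = "schemeless", owner = "lab-delta", repo = "foreign-kernels",
                section = "back", encoding = "text"))),
    list(pmc_id = "PMC900005", title = "Requirements that never resolve",
         journal = journals$jC, article_type = "research-article",
         date_published = "2020-11-30",
         links = list(
           list(dialect = "fragment", owner = "lab-delta", repo = "broken-reqs",
                section = "body", encoding = "ext-link"),
           list(dialect = "gist", owner = "lab-delta", repo = "broken-reqs",
                section = "body", encoding = "text"))),
    list(pmc_id = "PMC900006", title = "Odds, ends, and a vanished repository",
         journal = journals$jC, article_type = "tools-resources",
         date_published = "2021-09-05",
         mesh = c("Diseases"),
         links = list(
           list(dialect = "trailing_slash", owner = "lab-epsilon",
                repo = "odds-and-ends", section = "body", encoding = "text"),
           list(dialect = "plain", owner = "ghost-lab", repo = "vanished",
                section = "back", encoding = "ext-link"))),
    list(pmc_id = "PMC900007", title = "A minimal record"),
    list(pmc_id = "PMC900008", title = "Notebook-free companion study",
         journal = journals$jB, article_type = "research-article",
         date_published = "2019-05-17", mesh = c("Genomics"))
  )
  list(repos = repos, articles = articles,
       timeout_sleep = timeout_sleep,
       execution_timeout = execution_timeout,
       policy = list(default_version = "3.11", bundle = "forgepkg"))
}

#' Forge a complete labelled corpus
#'
#' Writes, under `out_dir`: `articles/` (JATS XML), `repos/{owner}/{repo}`
#' working trees, `index/` (the local package index), and `manifest.json`.
#' Deterministic: the same `(config, seed)` produces byte-identical trees
#' and manifests.
#'
#' @param out_dir Workspace directory (created; must be empty or absent).
#' @param seed Integer seed.
#' @param config A configuration from [default_forge_config()].
#' @return The manifest: a list with `seed`, `articles`, `links`, `repos`,
#'   `notebooks` (data.frames), and `policy` / `execution_timeout` (the
#'   matching pipeline settings).
#' @export
forge_corpus <- function(out_dir, seed = 1L, config = default_forge_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  publish_local_index(file.path(out_dir, "index"))

  nb_rows <- list()
  repo_rows <- list()
  for (repo in config$repos) {
    rows <- forge_repository(repo, file.path(out_dir, "repos"),
                             seed = seed, timeout_sleep = config$timeout_sleep)
    nb_rows[[length(nb_rows) + 1L]] <- rows
    repo_rows[[length(repo_rows) + 1L]] <- data.frame(
      canonical_url = paste0("https://github.com/", repo$owner, "/", repo$name),
      installable = isTRUE(repo$installable),
      has_requirements = "requirements" %in% repo$declarations,
      has_setup = "setup" %in% repo$declarations,
      has_pipfile = "pipfile" %in% repo$declarations,
      available = TRUE, stringsAsFactors = FALSE)
  }
  notebooks <- do.call(rbind, nb_rows)

  art_rows <- list(); link_rows <- list()
  for (art in config$articles) {
    forged <- forge_article(art, file.path(out_dir, "articles"), seed = seed)
    art_rows[[length(art_rows) + 1L]] <- forged$article
    link_rows[[length(link_rows) + 1L]] <- forged$links
  }
  articles <- do.call(rbind, art_rows)
  links <- do.call(rbind, link_rows)

  # the vanished repository is linked but never written
  repos <- do.call(rbind, repo_rows)
  repos <- rbind(repos, data.frame(
    canonical_url = "https://github.com/ghost-lab/vanished",
    installable = NA, has_requirements = NA, has_setup = NA, has_pipfile = NA,
    available = FALSE, stringsAsFactors = FALSE))

  manifest <- list(seed = seed, articles = articles, links = links,
                   repos = repos, notebooks = notebooks,
                   policy = config$policy,
                   execution_timeout = config$execution_timeout)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "columns", na = "null", auto_unbox = TRUE,
                       digits = NA)
  manifest
}

#' Read a forge manifest back from a corpus workspace
#'
#' @param out_dir A workspace written by [forge_corpus()].
#' @return The manifest list.
#' @export
read_manifest <- function(out_dir) {
  payload <- jsonlite::fromJSON(file.path(out_dir, "manifest.json"),
                                simplifyVector = TRUE)
  for (tab in c("articles", "links", "repos", "notebooks")) {
    payload[[tab]] <- as.data.frame(payload[[tab]], stringsAsFactors = FALSE)
  }
  payload
}
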
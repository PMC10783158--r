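# End-to-end pipeline: mine -> harvest -> profile -> environments -> execute
# -> classify, writing every record into the corpus store.

#' Run the full audit pipeline over a corpus workspace
#'
#' Expects a workspace laid out like the output of [forge_corpus()]:
#' `articles/` with one JATS XML per article, `repos/{owner}/{repo}` source
#' trees (for the offline acquisition backend), and optionally `index/` (the
#' local package index). Each stage writes its records to the store; the
#' flow-count conservation invariants are asserted at the end.
#'
#' @param workspace Corpus workspace directory.
#' @param store A [corpus_store()] (a fresh one by default).
#' @param vcs_backend Repository acquisition backend; defaults to
#'   [vcs_backend_local()] over `workspace/repos`.
#' @param env_backend Environment backend; defaults to
#'   [env_backend_local_index()] over `workspace/index`.
#' @param policy Environment policy ([default_env_policy()]); forged corpora
#'   carry the matching policy in their manifest.
#' @param timeout Per-notebook execution timeout in seconds (production
#'   default 3600; desk-scale corpora use the manifest's
#'   `execution_timeout`).
#' @param mesh_lookup Descriptor-to-top-level mapping ([load_mesh_lookup()]).
#' @param lang_detector,style_engine Injectable profilers.
#' @param strict_counters Identity policy for [classify_outcome()].
#' @param results_dir Optional directory receiving executed copies,
#'   mirroring repository paths.
#' @return The populated store, invisibly.
#' @export
run_pipeline <- function(workspace, store = corpus_store(),
                         vcs_backend = NULL, env_backend = NULL,
                         policy = default_env_policy(), timeout = 3600,
                         mesh_lookup = load_mesh_lookup(),
                         lang_detector = detect_language_stopwords,
                         style_engine = style_engine_default,
                         strict_counters = FALSE, results_dir = NULL) {
  stopifnot(dir.exists(workspace))
  if (is.null(vcs_backend)) vcs_backend <- vcs_backend_local(file.path(workspace, "repos"))
  if (is.null(env_backend)) env_backend <- env_backend_local_index(file.path(workspace, "index"))

  mine_articles(file.path(workspace, "articles"), store, mesh_lookup)
  repos <- harvest_repositories(store, file.path(workspace, "work"), vcs_backend)
  profile_notebooks(store, repos, lang_detector, style_engine)
  build_environments(store, repos, env_backend, workspace, policy)
  execute_corpus(store, repos, timeout, strict_counters, results_dir)
  flow_counts(store)  # asserts conservation
  invisible(store)
}

mine_articles <- function(xml_dir, store, mesh_lookup) {
  files <- sort(list.files(xml_dir, pattern = "\\.xml$", full.names = TRUE),
                method = "radix")
  registry <- journal_registry()
  for (path in files) {
    rec <- extract_article_metadata(read_jats(path), registry)
    upsert(store, "articles", data.frame(
      pmc_id = rec$pmc_id, pubmed_id = rec$pubmed_id, doi = rec$doi,
      title = rec$title, journal_id = rec$journal_id,
      publisher_name = rec$publisher_name, article_type = rec$article_type,
      date_received = rec$date_received, date_accepted = rec$date_accepted,
      date_published = rec$date_published, license_text = rec$license_text,
      copyright_text = rec$copyright_text,
      keywords = paste(rec$keywords, collapse = "|"),
      stringsAsFactors = FALSE))
    if (nrow(rec$repo_mentions) > 0L) {
      norm <- lapply(rec$repo_mentions$raw, normalize_repo_link)
      upsert(store, "article_links", data.frame(
        pmc_id = rec$pmc_id,
        raw = rec$repo_mentions$raw,
        section = rec$repo_mentions$section,
        canonical_url = vapply(norm, function(x)
          if (inherits(x, "nb_repo_link")) x$canonical_url else NA_character_,
          character(1)),
        source_form = vapply(norm, function(x)
          if (inherits(x, "nb_repo_link")) x$source_form else NA_character_,
          character(1)),
        rejection_reason = vapply(norm, function(x)
          if (inherits(x, "nb_link_rejection")) x$reason else NA_character_,
          character(1)),
        stringsAsFactors = FALSE))
    }
    if (length(rec$mesh_terms) > 0L) {
      upsert(store, "article_mesh", data.frame(
        pmc_id = rec$pmc_id, term = rec$mesh_terms,
        top_level = vapply(rec$mesh_terms, mesh_lookup, character(1)),
        stringsAsFactors = FALSE))
    }
    if (nrow(rec$authors) > 0L) {
      authors <- rec$authors
      authors$pmc_id <- rec$pmc_id
      upsert(store, "authors", authors)
    }
  }
  journals <- registry_journals(registry)
  if (nrow(journals) > 0L) upsert(store, "journals", journals)
  invisible(store)
}

harvest_repositories <- function(store, work_dir, vcs_backend) {
  links <- store_table(store, "article_links")
  accepted <- links[!is.na(links$canonical_url), , drop = FALSE]
  # deduplicate case-insensitively, keeping the first-seen spelling
  canon <- accepted$canonical_url[!duplicated(tolower(accepted$canonical_url))]
  repos <- list()
  for (url in canon) {
    parts <- strsplit(sub("^https://github\\.com/", "", url), "/")[[1]]
    link <- new_repo_link(parts[1], parts[2], "plain")
    repo <- acquire_repository(link, work_dir, vcs_backend)
    decl <- if (repo$available) detect_declarations(repo$local_path) else NULL
    upsert(store, "repositories", data.frame(
      canonical_url = repo$canonical_url, available = repo$available,
      local_path = repo$local_path, default_branch = repo$default_branch,
      has_requirements = decl$has_requirements %||% NA,
      has_setup = decl$has_setup %||% NA,
      has_pipfile = decl$has_pipfile %||% NA,
      stringsAsFactors = FALSE))
    repos[[url]] <- list(record = repo, declarations = decl)
    if (repo$available) {
      nbs <- enumerate_notebooks(repo$local_path)
      if (nrow(nbs) > 0L) {
        nbs$repo_url <- repo$canonical_url
        upsert(store, "notebooks", nbs)
      }
    }
  }
  repos
}

flatten_profile <- function(repo_url, relative_path, s, md, nm, imp) {
  data.frame(
    repo_url = repo_url, relative_path = relative_path,
    language = s$language, kernel_name = s$kernel_name,
    language_version_full = s$language_version_full,
    major_version = s$major_version,
    cells_total = s$cells_total, code_cells = s$code_cells,
    markdown_cells = s$markdown_cells, raw_cells = s$raw_cells,
    empty_cells = s$empty_cells, cells_with_output = s$cells_with_output,
    max_execution_count = s$max_execution_count,
    has_execution_counts = s$has_execution_counts,
    md_languages = paste(md$languages_detected, collapse = "|"),
    english_only = md$english_only,
    md_lines = md$total_lines, md_words = md$total_words,
    md_elements = paste(md$elements_present, collapse = "|"),
    title = nm$title, title_length = nm$title_length,
    posix_portable = nm$posix_portable,
    windows_disallowed = nm$windows_disallowed,
    is_untitled = nm$is_untitled, contains_copy = nm$contains_copy,
    contains_test = nm$contains_test,
    n_external_modules = if (is.null(imp)) NA_integer_ else length(imp$modules_external),
    n_local_modules = if (is.null(imp)) NA_integer_ else length(imp$modules_local),
    modules_external = if (is.null(imp)) NA_character_ else
      paste(imp$modules_external, collapse = "|"),
    modules_local = if (is.null(imp)) NA_character_ else
      paste(imp$modules_local, collapse = "|"),
    functions_defined = if (is.null(imp)) NA_integer_ else imp$functions_defined,
    classes_defined = if (is.null(imp)) NA_integer_ else imp$classes_defined,
    load_extensions = if (is.null(imp)) NA_character_ else
      paste(imp$load_extensions, collapse = "|"),
    syntax_ok = if (is.null(imp)) NA else imp$syntax_ok,
    stringsAsFactors = FALSE)
}

profile_notebooks <- function(store, repos, lang_detector, style_engine) {
  notebooks <- store_table(store, "notebooks")
  if (nrow(notebooks) == 0L) return(invisible(store))
  for (i in seq_len(nrow(notebooks))) {
    row <- notebooks[i, ]
    if (!identical(row$parse_status, "parsed")) next
    repo <- repos[[row$repo_url]]
    nb_path <- file.path(repo$record$local_path, row$relative_path)
    nb <- read_notebook(nb_path)
    s <- profile_structure(nb)
    md <- profile_markdown(nb, lang_detector)
    nm <- profile_name(row$relative_path)
    imp <- NULL
    if (identical(s$language, "python")) {
      imp <- profile_imports(nb, repo$record$local_path)
      style <- profile_style(nb, style_engine)
      if (nrow(style) > 0L) {
        style$repo_url <- row$repo_url
        style$relative_path <- row$relative_path
        upsert(store, "style_findings", style)
      }
    }
    upsert(store, "profiles",
           flatten_profile(row$repo_url, row$relative_path, s, md, nm, imp))
  }
  invisible(store)
}

build_environments <- function(store, repos, env_backend, workspace, policy) {
  profiles <- store_table(store, "profiles")
  if (nrow(profiles) == 0L) return(invisible(list()))
  outcomes <- list()
  py <- profiles[profiles$language == "python", , drop = FALSE]
  if (nrow(py) == 0L) return(invisible(list()))
  for (i in seq_len(nrow(py))) {
    row <- py[i, ]
    repo <- repos[[row$repo_url]]
    s <- base::structure(list(language = "python",
                              language_version_full = row$language_version_full),
                         class = "notebook_structure")
    spec <- plan_environment(s, repo$declarations, policy, scope = row$repo_url)
    if (is.null(outcomes[[spec$env_key]])) {
      out <- materialize_environment(spec, env_backend, workspace,
                                     repo$record$local_path,
                                     bundle = policy$bundle)
      outcomes[[spec$env_key]] <- out
      upsert(store, "environments", data.frame(
        env_key = spec$env_key, repo_url = row$repo_url,
        interpreter_version = spec$interpreter_version,
        dependency_source = spec$dependency_source,
        declaration_paths = paste(spec$declaration_paths, collapse = "|"),
        success = out$success, failed_stage = out$failed_stage,
        duration = out$duration, stringsAsFactors = FALSE))
    }
    attr(outcomes, "by_notebook") <- c(
      attr(outcomes, "by_notebook"),
      setNames(spec$env_key, paste(row$repo_url, row$relative_path)))
  }
  assign("env_outcomes", outcomes, envir = store)
  invisible(outcomes)
}

execute_corpus <- function(store, repos, timeout, strict_counters, results_dir) {
  notebooks <- store_table(store, "notebooks")
  if (nrow(notebooks) == 0L) return(invisible(store))
  profiles <- store_table(store, "profiles")
  env_outcomes <- get0("env_outcomes", envir = store, ifnotfound = list())
  env_by_nb <- attr(env_outcomes, "by_notebook") %||% character(0)

  for (i in seq_len(nrow(notebooks))) {
    row <- notebooks[i, ]
    repo <- repos[[row$repo_url]]$record
    key <- paste(row$repo_url, row$relative_path)
    prof <- profiles[profiles$repo_url == row$repo_url &
                       profiles$relative_path == row$relative_path, , drop = FALSE]

    if (!identical(row$parse_status, "parsed") || nrow(prof) == 0L) {
      outcome <- classify_outcome(repo, NULL)
      record_outcome(store, row, outcome)
      next
    }
    s <- base::structure(as.list(prof[1, ]), class = "notebook_structure")
    if (!identical(s$language, "python")) {
      outcome <- classify_outcome(repo, s)
      record_outcome(store, row, outcome)
      next
    }
    install <- env_outcomes[[env_by_nb[[key]]]]
    if (!isTRUE(install$success)) {
      outcome <- classify_outcome(repo, s, install)
      record_outcome(store, row, outcome)
      next
    }

    nb_path <- file.path(repo$local_path, row$relative_path)
    nb_dir <- dirname(nb_path)
    original <- read_notebook(nb_path)
    exec_input <- nb_path
    tmp_upgraded <- NULL
    if (!identical(original$nbformat, 4L)) {
      # legacy document: execute an upgraded copy beside the original
      tmp_upgraded <- file.path(nb_dir, paste0(".nbaudit-exec-", basename(nb_path)))
      write_notebook(original, tmp_upgraded)
      exec_input <- tmp_upgraded
    }
    before <- snapshot_workspace(nb_dir, exclude = basename(row$relative_path))
    trace <- execute_notebook(exec_input, install$handle, timeout = timeout)
    after <- snapshot_workspace(nb_dir, exclude = basename(row$relative_path))
    if (!is.null(tmp_upgraded)) unlink(tmp_upgraded)

    upsert(store, "executions", data.frame(
      repo_url = row$repo_url, relative_path = row$relative_path,
      duration = trace$duration, completed = trace$completed,
      timed_out = trace$timed_out,
      kernel_start_failed = trace$kernel_start_failed,
      ename = trace$first_exception_type,
      ename_canonical = trace$first_exception_canonical,
      exception_cell = trace$first_exception_cell,
      cells_executed = trace$cells_executed, stringsAsFactors = FALSE))

    diff <- NULL
    if (isTRUE(trace$completed)) {
      executed <- read_notebook(trace$executed_path)
      diff <- diff_against_original(original, executed, before, after)
      upsert(store, "diffs", data.frame(
        repo_url = row$repo_url, relative_path = row$relative_path,
        output_diff_count = diff$output_diff_count,
        execcount_diff_count = diff$execcount_diff_count,
        file_diff_count = diff$file_diff_count, stringsAsFactors = FALSE))
      if (!is.null(results_dir)) {
        dest <- file.path(results_dir, sub("^https://github\\.com/", "", row$repo_url),
                          row$relative_path)
        dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
        file.copy(trace$executed_path, dest, overwrite = TRUE)
      }
    }
    if (!is.null(trace$executed_path) && !is.na(trace$executed_path)) {
      unlink(trace$executed_path)
    }
    outcome <- classify_outcome(repo, s, install, trace, diff,
                                strict_counters = strict_counters)
    record_outcome(store, row, outcome)
  }
  invisible(store)
}

record_outcome <- function(store, nb_row, outcome) {
  upsert(store, "outcomes", data.frame(
    repo_url = nb_row$repo_url, relative_path = nb_row$relative_path,
    label = outcome$label, exception_type = outcome$exception_type,
    stringsAsFactors = FALSE))
}

#' Compare pipeline outcomes against a forge manifest
#'
#' Joins the store's outcome labels with the manifest's ground truth and
#' reports per-notebook agreement: the outcome label must equal the expected
#' label and, for exceptions, the canonical exception class must match.
#'
#' @param store A store populated by [run_pipeline()].
#' @param manifest A manifest from [forge_corpus()] / [read_manifest()].
#' @return A list with `table` (per-notebook comparison data.frame) and
#'   `recovery` (fraction of notebooks whose ground-truth label was
#'   recovered).
#' @export
recover_labels <- function(store, manifest) {
  outcomes <- store_table(store, "outcomes")
  truth <- manifest$notebooks
  merged <- merge(truth, outcomes, by = c("repo_url", "relative_path"),
                  all.x = TRUE)
  merged$match <- !is.na(merged$label) &
    merged$label == merged$expected_outcome &
    (merged$expected_outcome != "exception" |
       (!is.na(merged$exception_type) &
          merged$exception_type == merged$expected_exception))
  list(table = merged[, c("repo_url", "relative_path", "behavior",
                          "expected_outcome", "expected_exception",
                          "label", "exception_type", "match")],
       recovery = mean(merged$match))
}
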
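# Corpus store: a single in-memory relational store (data.frames keyed by
# natural keys) linking journals, articles, links, repositories, notebooks,
# profiles, environments, executions, diffs, style findings, and outcomes,
# with a single-file JSON dump/load and per-table CSV export.

STORE_SCHEMA_VERSION <- 1L

store_tables <- function() {
  list(
    journals = list(key = "journal_id"),
    articles = list(key = "pmc_id"),
    article_links = list(group = "pmc_id"),
    article_mesh = list(key = c("pmc_id", "term")),
    authors = list(group = "pmc_id"),
    repositories = list(key = "canonical_url", refs = NULL),
    notebooks = list(key = c("repo_url", "relative_path"),
                     refs = c(repo_url = "repositories.canonical_url")),
    profiles = list(key = c("repo_url", "relative_path"),
                    refs = c(repo_url = "repositories.canonical_url")),
    style_findings = list(group = c("repo_url", "relative_path")),
    environments = list(key = "env_key"),
    executions = list(key = c("repo_url", "relative_path")),
    diffs = list(key = c("repo_url", "relative_path")),
    outcomes = list(key = c("repo_url", "relative_path"),
                    refs = c(repo_url = "repositories.canonical_url"))
  )
}

#' Create an empty corpus store
#'
#' The store holds one data.frame per entity table. Upserts are idempotent on
#' each table's natural key (PMC id, canonical repository URL, repository +
#' path); percentages and flow counts are always computed by queries at read
#' time, never cached.
#'
#' @return An environment of class `corpus_store`.
#' @export
corpus_store <- function() {
  store <- new.env(parent = emptyenv())
  store$schema_version <- STORE_SCHEMA_VERSION
  store$tables <- lapply(store_tables(), function(cfg) NULL)
  class(store) <- "corpus_store"
  store
}

#' @export
print.corpus_store <- function(x, ...) {
  cat("<corpus_store>\n")
  for (tab in names(x$tables)) {
    n <- if (is.null(x$tables[[tab]])) 0L else nrow(x$tables[[tab]])
    cat(sprintf("  %-14s %6d rows\n", tab, n))
  }
  invisible(x)
}

#' Insert or update rows in a store table
#'
#' Idempotent on the table's natural key: re-upserting the same key replaces
#' the row. Append-style tables (links, authors, style findings) are
#' replaced as a group per owning entity. Referential integrity to the parent
#' table is checked and violations are rejected with the violated clause
#' named.
#'
#' @param store A [corpus_store()].
#' @param table Table name.
#' @param rows A data.frame of rows (may be a single row).
#' @return The store, invisibly.
#' @export
upsert <- function(store, table, rows) {
  stopifnot(inherits(store, "corpus_store"))
  cfg <- store_tables()[[table]]
  if (is.null(cfg)) stop("unknown table: ", table, call. = FALSE)
  stopifnot(is.data.frame(rows))
  if (nrow(rows) == 0L) return(invisible(store))

  if (!is.null(cfg$refs)) {
    for (col in names(cfg$refs)) {
      target <- strsplit(cfg$refs[[col]], ".", fixed = TRUE)[[1]]
      parent <- store$tables[[target[1]]]
      known <- if (is.null(parent)) character(0) else parent[[target[2]]]
      missing <- setdiff(unique(rows[[col]]), known)
      if (length(missing) > 0L) {
        stop(sprintf("referential integrity violated: %s.%s -> %s has no %s",
                     table, col, cfg$refs[[col]],
                     paste(missing, collapse = ", ")), call. = FALSE)
      }
    }
  }

  existing <- store$tables[[table]]
  if (is.null(existing)) {
    store$tables[[table]] <- rows
    return(invisible(store))
  }
  # align columns
  for (col in setdiff(names(existing), names(rows))) rows[[col]] <- NA
  for (col in setdiff(names(rows), names(existing))) existing[[col]] <- NA
  rows <- rows[names(existing)]

  keycols <- cfg$key %||% cfg$group
  oldkeys <- do.call(paste, c(existing[keycols], sep = "\r"))
  newkeys <- do.call(paste, c(rows[keycols], sep = "\r"))
  keep <- !(oldkeys %in% newkeys)
  store$tables[[table]] <- rbind(existing[keep, , drop = FALSE], rows)
  rownames(store$tables[[table]]) <- NULL
  invisible(store)
}

#' Fetch a store table
#'
#' @param store A [corpus_store()].
#' @param table Table name.
#' @return The table's data.frame (zero-row placeholder when empty).
#' @export
store_table <- function(store, table) {
  tab <- store$tables[[table]]
  if (is.null(tab)) return(data.frame())
  tab
}

#' Stage-by-stage flow counts
#'
#' Recomputes the corpus flow (articles, linked / available / notebook-bearing
#' repositories, notebooks by language, attempted, install failures,
#' executions, exceptions, exclusions, finished identical / different) by
#' queries over the store, and asserts the conservation invariants
#' `attempted = install_failed + executed`,
#' `executed = exceptions + excluded + timeouts + finished`, and
#' `finished = identical + different` before returning. An invariant failure
#' raises a diagnostic naming the offending notebooks.
#'
#' @param store A [corpus_store()].
#' @return A named list of class `flow_counts`.
#' @export
flow_counts <- function(store) {
  articles <- store_table(store, "articles")
  links <- store_table(store, "article_links")
  repos <- store_table(store, "repositories")
  notebooks <- store_table(store, "notebooks")
  profiles <- store_table(store, "profiles")
  outcomes <- store_table(store, "outcomes")

  accepted_links <- if (nrow(links)) links[!is.na(links$canonical_url), ] else links
  n_label <- function(labels) {
    if (nrow(outcomes) == 0L) 0L else sum(outcomes$label %in% labels)
  }
  counts <- list(
    articles = nrow(articles),
    repos_linked = if (nrow(accepted_links)) length(unique(tolower(accepted_links$canonical_url))) else 0L,
    repos_available = if (nrow(repos)) sum(repos$available) else 0L,
    repos_with_notebooks = if (nrow(repos) && nrow(notebooks))
      length(unique(notebooks$repo_url)) else 0L,
    notebooks_total = nrow(notebooks),
    notebooks_target_language = if (nrow(profiles)) sum(profiles$language == "python") else 0L,
    notebooks_attempted = n_label(c("install_failed", "exception", "timeout",
                                    "excluded", "finished_identical",
                                    "finished_different")),
    install_failed = n_label("install_failed"),
    executed = n_label(c("exception", "timeout", "excluded",
                         "finished_identical", "finished_different")),
    exceptions = n_label("exception"),
    timeouts = n_label("timeout"),
    excluded = n_label("excluded"),
    finished = n_label(c("finished_identical", "finished_different")),
    finished_identical = n_label("finished_identical"),
    finished_different = n_label("finished_different")
  )
  check <- function(cond, msg) {
    if (!cond) {
      bad <- if (nrow(outcomes)) paste(utils::head(paste0(outcomes$repo_url, ":",
                                                          outcomes$relative_path), 10),
                                       collapse = "; ") else ""
      stop("flow invariant violated: ", msg, " [", bad, "]", call. = FALSE)
    }
  }
  check(counts$notebooks_attempted == counts$install_failed + counts$executed,
        "attempted = install_failed + executed")
  check(counts$executed == counts$exceptions + counts$timeouts +
          counts$excluded + counts$finished,
        "executed = exceptions + timeouts + excluded + finished")
  check(counts$finished == counts$finished_identical + counts$finished_different,
        "finished = identical + different")
  check(counts$repos_with_notebooks <= counts$repos_available,
        "repos_with_notebooks <= repos_available")
  base::structure(counts, class = "flow_counts")
}

#' Dump a store to a single JSON file / load it back
#'
#' The dump/reload round trip preserves every table's rows exactly.
#'
#' @param store A [corpus_store()].
#' @param path JSON file path.
#' @return `store_dump` returns `path` invisibly; `store_load` returns a
#'   rebuilt [corpus_store()].
#' @export
store_dump <- function(store, path) {
  tables <- Filter(Negate(is.null), store$tables)
  tables <- lapply(tables, function(df) { rownames(df) <- NULL; df })
  payload <- list(schema_version = store$schema_version, tables = tables)
  jsonlite::write_json(payload, path, dataframe = "columns", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname store_dump
#' @export
store_load <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  store <- corpus_store()
  store$schema_version <- payload$schema_version
  for (tab in names(payload$tables)) {
    cols <- payload$tables[[tab]]
    store$tables[[tab]] <- as.data.frame(cols, stringsAsFactors = FALSE)
  }
  store
}

#' Export every populated table as CSV
#'
#' @param store A [corpus_store()].
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
store_export_csv <- function(store, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (tab in names(store$tables)) {
    df <- store$tables[[tab]]
    if (is.null(df) || nrow(df) == 0L) next
    path <- file.path(dir, paste0(tab, ".csv"))
    write_table_csv(df, path)
    written <- c(written, path)
  }
  invisible(written)
}
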
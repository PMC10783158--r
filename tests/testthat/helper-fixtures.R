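# Shared fixtures. Notebook documents for oracle tests are built as plain
# lists and serialized with jsonlite directly, independent of the package's
# own notebook writer.

h_cell <- function(type, source, outputs = NULL, ec = NULL) {
  cell <- list(cell_type = type, metadata = setNames(list(), character(0)),
               source = source)
  if (identical(type, "code")) {
    cell$outputs <- outputs %||% list()
    cell$execution_count <- ec
  }
  cell
}

h_stream <- function(text) list(output_type = "stream", name = "stdout", text = text)

h_notebook <- function(cells, kernel = "python3", language = "python",
                       version = "3.11") {
  metadata <- setNames(list(), character(0))
  if (!is.null(kernel)) {
    metadata <- list(kernelspec = list(name = kernel, display_name = kernel,
                                       language = language))
    if (!is.null(version)) {
      metadata$language_info <- list(name = language, version = version)
    }
  }
  list(nbformat = 4L, nbformat_minor = 5L, metadata = metadata, cells = cells)
}

h_write_nb <- function(nb, path = tempfile(fileext = ".ipynb")) {
  writeLines(jsonlite::toJSON(nb, auto_unbox = TRUE, null = "null"), path)
  path
}

h_python_handle <- function() list(python = Sys.which("python"))

`%||%` <- function(x, y) if (is.null(x)) y else x

# Behavior-labelled corpus audited once per test session and shared by the
# forge, analytics, and acceptance tests.
corpus_cache <- new.env()

shared_audit <- function() {
  if (is.null(corpus_cache$result)) {
    ws <- file.path(tempdir(), "nbaudit-shared-corpus")
    unlink(ws, recursive = TRUE)
    manifest <- forge_corpus(ws, seed = 1L)
    store <- corpus_store()
    run_pipeline(ws, store,
                 policy = default_env_policy(bundle = manifest$policy$bundle),
                 timeout = manifest$execution_timeout)
    corpus_cache$result <- list(workspace = ws, manifest = manifest,
                                store = store)
  }
  corpus_cache$result
}

# The link-dialect table: raw form, expected canonical URL (NA = rejection),
# expected source form or rejection reason.
link_dialect_cases <- function() {
  rbind(
    data.frame(raw = "https://github.com/user/repo",
               canonical = "https://github.com/user/repo", form = "plain"),
    data.frame(raw = "https://github.com/user/repo/",
               canonical = "https://github.com/user/repo", form = "plain"),
    data.frame(raw = "http://github.com/user/repo",
               canonical = "https://github.com/user/repo", form = "plain"),
    data.frame(raw = "github.com/user/repo",
               canonical = "https://github.com/user/repo", form = "plain"),
    data.frame(raw = "https://www.github.com/user/repo",
               canonical = "https://github.com/user/repo", form = "plain"),
    data.frame(raw = "https://github.com/user/repo#readme",
               canonical = "https://github.com/user/repo", form = "plain"),
    data.frame(raw = "https://github.com/user/repo?tab=readme",
               canonical = "https://github.com/user/repo", form = "plain"),
    data.frame(raw = "https://github.com/user/repo.git",
               canonical = "https://github.com/user/repo", form = "git_suffix"),
    data.frame(raw = "https://github.com/user/repo/blob/main/nb.ipynb",
               canonical = "https://github.com/user/repo", form = "blob_path"),
    data.frame(raw = "https://github.com/user/repo/tree/master/src",
               canonical = "https://github.com/user/repo", form = "tree_path"),
    data.frame(raw = "https://github.com/user/repo/raw/main/data.csv",
               canonical = "https://github.com/user/repo", form = "other"),
    data.frame(raw = "https://nbviewer.jupyter.org/github/user/repo/blob/master/x.ipynb",
               canonical = "https://github.com/user/repo", form = "nbviewer"),
    data.frame(raw = "https://nbviewer.org/github/user/repo/tree/main",
               canonical = "https://github.com/user/repo", form = "nbviewer"),
    data.frame(raw = "https://raw.githubusercontent.com/user/repo/main/requirements.txt",
               canonical = "https://github.com/user/repo", form = "raw_host"),
    data.frame(raw = "https://github.com/user",
               canonical = NA_character_, form = "owner_only"),
    data.frame(raw = "https://user.github.io/project",
               canonical = NA_character_, form = "pages_site"),
    data.frame(raw = "https://gist.github.com/user/abc123",
               canonical = NA_character_, form = "non_repo_host"),
    data.frame(raw = "https://github.com/",
               canonical = NA_character_, form = "malformed"),
    data.frame(raw = "https://example.com/user/repo",
               canonical = NA_character_, form = "non_repo_host")
  )
}
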
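# Repository harvesting: acquire the default branch of each linked repository,
# record availability, and enumerate candidate notebooks.

#' Directory-copy acquisition backend
#'
#' Resolves a canonical repository URL against a local directory laid out as
#' `root/{owner}/{repo}` and copies the tree into the harvest workspace. This
#' is the offline backend used with forged corpora; the contract is the one
#' every backend implements: a function `(canonical_url, dest_dir)` returning
#' `list(path, default_branch)` on success or `NULL` when the remote does not
#' exist.
#'
#' @param root Directory containing `{owner}/{repo}` source trees.
#' @return A backend function.
#' @export
vcs_backend_local <- function(root) {
  force(root)
  function(canonical_url, dest_dir) {
    rel <- sub("^https://github\\.com/", "", canonical_url)
    src <- file.path(root, rel)
    if (!dir.exists(src)) return(NULL)
    dir.create(dest_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list.files(src, recursive = TRUE, all.files = TRUE, no.. = TRUE)
    for (f in files) {
      target <- file.path(dest_dir, f)
      dir.create(dirname(target), recursive = TRUE, showWarnings = FALSE)
      file.copy(file.path(src, f), target, overwrite = TRUE)
    }
    list(path = dest_dir, default_branch = "main")
  }
}

#' Git acquisition backend
#'
#' Shallow-clones the default branch with the `git` command-line client
#' (`--depth 1`; full history is not needed, commit counts come from the
#' hosting API payload, not from history). A failed clone is reported as an
#' unavailable remote, not an error.
#'
#' @param git Path to the git executable.
#' @return A backend function (see [vcs_backend_local()] for the contract).
#' @export
vcs_backend_git <- function(git = Sys.which("git")) {
  force(git)
  function(canonical_url, dest_dir) {
    status <- suppressWarnings(system2(
      git, c("clone", "--depth", "1", "--quiet", shQuote(canonical_url),
             shQuote(dest_dir)),
      stdout = FALSE, stderr = FALSE))
    if (!identical(status, 0L) || !dir.exists(dest_dir)) return(NULL)
    branch <- suppressWarnings(system2(
      git, c("-C", shQuote(dest_dir), "rev-parse", "--abbrev-ref", "HEAD"),
      stdout = TRUE, stderr = FALSE))
    list(path = dest_dir, default_branch = trimws(branch[1] %||% "main"))
  }
}

#' Acquire one linked repository
#'
#' Materializes the default branch of the repository behind a normalized link
#' into the harvest workspace. A missing remote is a recorded observation
#' ("page not found" repositories are part of the corpus), not an error; only
#' workspace I/O failures raise.
#'
#' @param link An `nb_repo_link` from [normalize_repo_link()].
#' @param workspace Writable directory for harvested working trees.
#' @param vcs_backend Acquisition function, e.g. [vcs_backend_local()].
#' @return A list of class `repository_record` with `canonical_url`,
#'   `available`, `local_path` (`NA` when unavailable), and
#'   `default_branch`. Re-acquiring into an unchanged workspace reuses the
#'   existing working tree (idempotent harvest).
#' @export
acquire_repository <- function(link, workspace, vcs_backend) {
  stopifnot(inherits(link, "nb_repo_link"))
  if (!dir.exists(workspace)) {
    dir.create(workspace, recursive = TRUE)
    if (!dir.exists(workspace)) stop("cannot create workspace: ", workspace)
  }
  dest <- file.path(workspace, link$owner, link$repo_name)
  if (dir.exists(dest)) {
    return(structure(list(canonical_url = link$canonical_url, available = TRUE,
                          local_path = dest, default_branch = "main"),
                     class = "repository_record"))
  }
  res <- vcs_backend(link$canonical_url, dest)
  if (is.null(res)) {
    return(structure(list(canonical_url = link$canonical_url, available = FALSE,
                          local_path = NA_character_,
                          default_branch = NA_character_),
                     class = "repository_record"))
  }
  structure(list(canonical_url = link$canonical_url, available = TRUE,
                 local_path = res$path, default_branch = res$default_branch),
            class = "repository_record")
}

#' Enumerate candidate notebooks in a working tree
#'
#' Recursively lists `.ipynb` files in deterministic lexicographic order,
#' excluding hidden directories (`.git`, `.ipynb_checkpoints`) and symbolic
#' links. Each file is test-loaded against the notebook schema.
#'
#' @param repo_root Repository working tree.
#' @param size_cap_bytes Files above this size are recorded but not parsed.
#' @return A data.frame with `relative_path`, `file_size`, and `parse_status`
#'   (`parsed`, `invalid_json`, or `invalid_schema`).
#' @export
enumerate_notebooks <- function(repo_root, size_cap_bytes = 64 * 1024^2) {
  stopifnot(dir.exists(repo_root))
  files <- list.files(repo_root, pattern = "\\.ipynb$", recursive = TRUE,
                      all.files = TRUE, no.. = TRUE)
  # exclude anything under a hidden directory
  hidden <- vapply(strsplit(files, "/", fixed = TRUE), function(parts) {
    any(startsWith(parts, "."))
  }, logical(1))
  files <- sort(files[!hidden], method = "radix")
  if (length(files) == 0L) {
    return(data.frame(relative_path = character(0), file_size = numeric(0),
                      parse_status = character(0), stringsAsFactors = FALSE))
  }
  full <- file.path(repo_root, files)
  islink <- !is.na(Sys.readlink(full)) & nzchar(Sys.readlink(full))
  files <- files[!islink]; full <- full[!islink]
  sizes <- file.size(full)
  status <- vapply(seq_along(full), function(i) {
    if (sizes[i] > size_cap_bytes) return("invalid_json")
    nb <- read_notebook(full[i])
    if (is_parse_failure(nb)) nb$status else "parsed"
  }, character(1))
  data.frame(relative_path = files, file_size = sizes, parse_status = status,
             stringsAsFactors = FALSE)
}

#' Ingest a hosting-API metadata payload
#'
#' Copies the recognized fields of a repository-metadata payload (creation /
#' update / push dates, language census, subscriber / fork / issue / release /
#' commit counts, license) into a flat record. Unknown keys are ignored and
#' absent keys are reported as `NA`, never invented.
#'
#' @param payload A named list, as decoded from a hosting-API JSON response.
#' @return A named list of the recognized fields.
#' @export
ingest_repo_metadata <- function(payload) {
  stopifnot(is.list(payload))
  num_or_na <- function(key) {
    v <- payload[[key]]
    if (is.null(v)) return(NA_real_)
    v <- as.numeric(v)
    if (!is.na(v) && v < 0) stop("negative count for ", key, call. = FALSE)
    v
  }
  list(
    created = scalar_or_na(payload$created_at),
    updated = scalar_or_na(payload$updated_at),
    pushed = scalar_or_na(payload$pushed_at),
    language_census = if (is.null(payload$languages)) NA_character_ else
      jsonlite::toJSON(payload$languages, auto_unbox = TRUE),
    subscribers = num_or_na("subscribers_count"),
    forks = num_or_na("forks_count"),
    issues = num_or_na("open_issues_count"),
    releases = num_or_na("releases_count"),
    commits_after_published = num_or_na("commits_after_published"),
    commits_after_accepted = num_or_na("commits_after_accepted"),
    commits_after_received = num_or_na("commits_after_received"),
    license_name = scalar_or_na(payload$license$name)
  )
}
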
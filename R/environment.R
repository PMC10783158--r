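# Environment reconstruction: detect dependency declarations, plan an
# interpreter + dependency source per notebook, materialize it.

#' Detect dependency declarations in a repository
#'
#' Case-insensitive filename match at any depth for `requirements.txt` (and
#' `*-requirements.txt` variants), `setup.py`, and `Pipfile`.
#'
#' @param repo_root Repository working tree.
#' @return A list of class `declaration_set` with `has_requirements`,
#'   `has_setup`, `has_pipfile`, and the sorted `declaration_paths`.
#' @export
detect_declarations <- function(repo_root) {
  stopifnot(dir.exists(repo_root))
  files <- list.files(repo_root, recursive = TRUE, all.files = FALSE, no.. = TRUE)
  base <- tolower(basename(files))
  req <- files[base == "requirements.txt" | grepl("requirements\\.txt$", base)]
  setup <- files[base == "setup.py"]
  pip <- files[base == "pipfile"]
  paths <- sort(c(req, setup, pip), method = "radix")
  structure(list(
    has_requirements = length(req) > 0L,
    has_setup = length(setup) > 0L,
    has_pipfile = length(pip) > 0L,
    declaration_paths = paths
  ), class = "declaration_set")
}

#' Plan an execution environment for a notebook
#'
#' The interpreter version is the notebook's declared version at minor
#' precision; an absent or unknown version falls back to the policy default.
#' When the repository declares dependencies, they are the dependency source;
#' otherwise the plan falls back to the configured distribution bundle (the
#' full data-science distribution set).
#'
#' @param structure A `notebook_structure` for a target-language notebook.
#' @param declarations A `declaration_set` for the repository.
#' @param policy List with `default_version` (newest supported 3.x) and
#'   `bundle` (character vector naming the distribution-bundle packages).
#' @param scope Environment granularity scope, normally the repository's
#'   canonical URL: one environment per (repository, interpreter version,
#'   declaration set). Enters the `env_key`.
#' @return A list of class `environment_spec` with `interpreter_version`,
#'   `dependency_source`, `declaration_paths`, and the deterministic
#'   `env_key` (a pure hash of the other fields).
#' @export
plan_environment <- function(structure, declarations,
                             policy = default_env_policy(), scope = NULL) {
  stopifnot(inherits(structure, "notebook_structure"))
  version <- structure$language_version_full
  minor <- if (!is.na(version) && grepl("^[0-9]+\\.[0-9]+", version)) {
    sub("^([0-9]+\\.[0-9]+).*$", "\\1", version)
  } else {
    policy$default_version
  }
  declared <- length(declarations$declaration_paths) > 0L
  spec <- list(
    interpreter_version = minor,
    dependency_source = if (declared) "declared" else "distribution_bundle",
    declaration_paths = declarations$declaration_paths,
    scope = scope
  )
  spec$env_key <- rlang::hash(spec)
  base::structure(spec, class = "environment_spec")
}

#' Default environment policy
#'
#' @param default_version Interpreter used when a notebook declares none.
#' @param bundle Package names standing in for the full data-science
#'   distribution set used as the no-declaration fallback.
#' @return A policy list for [plan_environment()].
#' @export
default_env_policy <- function(default_version = "3.11",
                               bundle = c("numpy", "pandas", "matplotlib",
                                          "scikit-learn", "scipy")) {
  list(default_version = default_version, bundle = bundle)
}

normalize_dist_name <- function(x) gsub("[._]", "-", tolower(trimws(x)))

# Extract declared distribution names from requirement files.
declared_requirements <- function(repo_root, declaration_paths) {
  names_out <- character(0)
  for (rel in declaration_paths) {
    path <- file.path(repo_root, rel)
    if (!file.exists(path)) next
    base <- tolower(basename(rel))
    lines <- readLines(path, warn = FALSE)
    if (grepl("requirements\\.txt$", base)) {
      lines <- sub("#.*$", "", lines)
      lines <- trimws(lines)
      lines <- lines[nzchar(lines) & !startsWith(lines, "-")]
      names_out <- c(names_out, sub("[\\[<>=!~; ].*$", "", lines))
    } else if (identical(base, "pipfile")) {
      in_pkgs <- FALSE
      for (ln in lines) {
        ln <- trimws(ln)
        if (grepl("^\\[", ln)) { in_pkgs <- identical(tolower(ln), "[packages]"); next }
        if (in_pkgs && grepl("=", ln, fixed = TRUE)) {
          names_out <- c(names_out, gsub('"', "", trimws(sub("=.*$", "", ln))))
        }
      }
    } else if (identical(base, "setup.py")) {
      text <- paste(lines, collapse = "\n")
      m <- regmatches(text, regexpr("install_requires\\s*=\\s*\\[[^]]*\\]", text))
      if (length(m)) {
        entries <- regmatches(m, gregexpr("[\"']([^\"']+)[\"']", m))[[1]]
        entries <- gsub("[\"']", "", entries)
        names_out <- c(names_out, sub("[\\[<>=!~; ].*$", "", entries))
      }
    }
  }
  unique(normalize_dist_name(names_out[nzchar(names_out)]))
}

#' Local-index environment backend
#'
#' Resolves declared requirements against a local package index (a directory
#' with one subdirectory per published distribution, as created by
#' [publish_local_index()]) and runs notebooks on the system interpreter.
#' Installation succeeds exactly when every declared name is present in the
#' index; a missing name is an install failure, recorded, never a crash. A
#' `null` variant ([env_backend_null()]) records the plan without resolving.
#'
#' @param index_dir Local package index directory.
#' @return A backend list with `create(version)` and
#'   `install(handle, repo_root, declaration_paths, bundle)` functions.
#' @export
env_backend_local_index <- function(index_dir) {
  force(index_dir)
  list(
    name = "local_index",
    create = function(version) {
      list(python = nbaudit_python(), requested_version = version)
    },
    install = function(handle, repo_root, declaration_paths, bundle) {
      wanted <- if (length(declaration_paths) > 0L) {
        declared_requirements(repo_root, declaration_paths)
      } else {
        normalize_dist_name(bundle)
      }
      available <- normalize_dist_name(list.dirs(index_dir, recursive = FALSE,
                                                 full.names = FALSE))
      missing <- setdiff(wanted, available)
      if (length(missing) == 0L) {
        list(success = TRUE, log = sprintf("resolved %d requirement(s) from local index",
                                           length(wanted)))
      } else {
        list(success = FALSE,
             log = paste0("No matching distribution found for: ",
                          paste(missing, collapse = ", ")))
      }
    }
  )
}

#' @rdname env_backend_local_index
#' @export
env_backend_null <- function() {
  list(
    name = "null",
    create = function(version) list(python = nbaudit_python(),
                                    requested_version = version),
    install = function(handle, repo_root, declaration_paths, bundle) {
      list(success = TRUE, log = "null backend: plan recorded, nothing built")
    }
  )
}

#' Materialize a planned environment
#'
#' Builds (or reuses) the environment for a spec via the injected backend.
#' Outcomes are cached by `env_key` under `workspace`: the same spec is never
#' built twice, and the cached outcome is returned with a near-zero duration.
#'
#' @param spec An `environment_spec`.
#' @param backend An environment backend (see [env_backend_local_index()]).
#' @param workspace Writable cache directory.
#' @param repo_root Repository working tree holding the declaration files.
#' @param bundle Distribution-bundle package names used when the spec's
#'   dependency source is the bundle fallback.
#' @return A list of class `install_outcome` with `success`, `failed_stage`
#'   (`create`, `install`, or `none`), `log_excerpt`, `duration`, `cached`,
#'   and `handle` (interpreter handle for the execution engine).
#' @export
materialize_environment <- function(spec, backend, workspace, repo_root,
                                    bundle = default_env_policy()$bundle) {
  stopifnot(inherits(spec, "environment_spec"))
  if (is.null(backend$create) || is.null(backend$install)) {
    stop("environment backend must provide create() and install()", call. = FALSE)
  }
  cache_dir <- file.path(workspace, "env-cache")
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  cache_file <- file.path(cache_dir, paste0(spec$env_key, ".json"))
  if (file.exists(cache_file)) {
    cached <- jsonlite::fromJSON(cache_file, simplifyVector = TRUE)
    t0 <- Sys.time()
    handle <- backend$create(spec$interpreter_version)
    out <- list(success = cached$success, failed_stage = cached$failed_stage,
                log_excerpt = cached$log_excerpt,
                duration = as.numeric(Sys.time() - t0, units = "secs"),
                cached = TRUE, handle = handle)
    return(structure(out, class = "install_outcome"))
  }
  t0 <- Sys.time()
  handle <- tryCatch(backend$create(spec$interpreter_version), error = function(e) e)
  if (inherits(handle, "error")) {
    out <- list(success = FALSE, failed_stage = "create",
                log_excerpt = conditionMessage(handle),
                duration = as.numeric(Sys.time() - t0, units = "secs"),
                cached = FALSE, handle = NULL)
  } else {
    res <- backend$install(handle, repo_root, spec$declaration_paths, bundle)
    out <- list(success = isTRUE(res$success),
                failed_stage = if (isTRUE(res$success)) "none" else "install",
                log_excerpt = res$log %||% "",
                duration = as.numeric(Sys.time() - t0, units = "secs"),
                cached = FALSE,
                handle = if (isTRUE(res$success)) handle else NULL)
  }
  jsonlite::write_json(out[c("success", "failed_stage", "log_excerpt")],
                       cache_file, auto_unbox = TRUE)
  structure(out, class = "install_outcome")
}
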
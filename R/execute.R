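# Re-execution of notebooks, output diffing, and outcome classification.

EXCEPTION_ALIASES <- c(
  IOError = "OSError", EnvironmentError = "OSError", WindowsError = "OSError",
  socket.error = "OSError"
)

#' Canonicalize a reported exception class name
#'
#' Modern interpreters alias `IOError` (and friends) to `OSError`; the
#' reported ename is kept verbatim elsewhere, this maps it onto the canonical
#' class for classification and aggregation.
#'
#' @param ename Exception class name string.
#' @return Canonical class name.
#' @export
canonical_exception <- function(ename) {
  if (is.na(ename)) return(NA_character_)
  if (ename %in% names(EXCEPTION_ALIASES)) unname(EXCEPTION_ALIASES[[ename]])
  else ename
}

#' Snapshot the files under a directory
#'
#' Name, size, and content digest of every file, used to detect files a
#' notebook creates or modifies during re-execution.
#'
#' @param dir Directory to snapshot.
#' @param exclude Relative paths to ignore (e.g. the notebook itself).
#' @return A data.frame with `path`, `size`, `md5`.
#' @export
snapshot_workspace <- function(dir, exclude = character(0)) {
  files <- list.files(dir, recursive = TRUE, all.files = TRUE, no.. = TRUE)
  files <- setdiff(files, exclude)
  files <- files[!grepl("(^|/)\\.", files) & !grepl("(^|/)__pycache__/", files)]
  if (length(files) == 0L) {
    return(data.frame(path = character(0), size = numeric(0), md5 = character(0),
                      stringsAsFactors = FALSE))
  }
  full <- file.path(dir, files)
  data.frame(path = files, size = file.size(full),
             md5 = unname(tools::md5sum(full)), stringsAsFactors = FALSE)
}

#' Re-execute a notebook once, top to bottom
#'
#' Runs every code cell exactly once, in document order, in a fresh
#' interpreter from the materialized environment, with the working directory
#' set to the notebook's directory. Execution stops at the first raised
#' exception; a wall-clock timeout aborts the run. The executed copy is
#' written to `executed_path` (the original file is never modified).
#'
#' @param nb_path Path to the notebook file.
#' @param env_handle Interpreter handle from [materialize_environment()]
#'   (list with element `python`).
#' @param timeout Wall-clock limit in seconds (default 3600; desk-scale runs
#'   use far less).
#' @param executed_path Where to write the executed document; defaults to a
#'   temporary file.
#' @return A list of class `execution_trace` with `started`, `finished`,
#'   `duration`, `completed`, `timed_out`, `kernel_start_failed`,
#'   `first_exception_type` (verbatim ename), `first_exception_canonical`,
#'   `first_exception_cell` (0-based code-cell ordinal), `cells_executed`,
#'   and `executed_path`.
#' @export
execute_notebook <- function(nb_path, env_handle, timeout = 3600,
                             executed_path = tempfile(fileext = ".ipynb")) {
  stopifnot(file.exists(nb_path), is.list(env_handle), !is.null(env_handle$python))
  trace_path <- tempfile(fileext = ".json")
  started <- Sys.time()
  status <- suppressWarnings(system2(
    env_handle$python,
    c(shQuote(python_helper("run_notebook.py")), shQuote(normalizePath(nb_path)),
      shQuote(executed_path), shQuote(trace_path), as.character(timeout)),
    stdout = FALSE, stderr = FALSE, timeout = ceiling(timeout * 3 + 10)))
  finished <- Sys.time()
  if (!file.exists(trace_path)) {
    # interpreter never produced a trace: kernel failed to start
    return(base::structure(list(
      started = started, finished = finished,
      duration = as.numeric(finished - started, units = "secs"),
      completed = FALSE, timed_out = FALSE, kernel_start_failed = TRUE,
      first_exception_type = NA_character_,
      first_exception_canonical = NA_character_,
      first_exception_cell = NA_integer_, cells_executed = 0L,
      executed_path = NA_character_), class = "execution_trace"))
  }
  tr <- jsonlite::fromJSON(trace_path, simplifyVector = TRUE)
  ename <- tr$first_exception_type %||% NA_character_
  if (is.null(tr$first_exception_type)) ename <- NA_character_
  out <- list(
    started = started, finished = finished,
    duration = tr$duration %||% as.numeric(finished - started, units = "secs"),
    completed = isTRUE(tr$completed),
    timed_out = isTRUE(tr$timed_out),
    kernel_start_failed = isTRUE(tr$kernel_start_failed),
    first_exception_type = ename,
    first_exception_canonical = canonical_exception(ename),
    first_exception_cell = if (is.null(tr$first_exception_cell)) NA_integer_
                           else as.integer(tr$first_exception_cell),
    cells_executed = as.integer(tr$cells_executed %||% 0L),
    executed_path = executed_path
  )
  if (isTRUE(out$completed)) {
    stopifnot(is.na(out$first_exception_type), !out$timed_out)
  }
  if (!is.na(out$first_exception_cell)) {
    stopifnot(out$cells_executed == out$first_exception_cell + 1L)
  }
  base::structure(out, class = "execution_trace")
}

# Normalize one output item to comparable text. Image/binary payloads are
# reduced to a digest of the decoded bytes.
normalize_output <- function(output, mask_transients = FALSE) {
  type <- output$output_type %||% ""
  if (identical(type, "stream")) {
    txt <- collapse_source(output$text)
  } else if (type %in% c("execute_result", "display_data")) {
    data <- output$data %||% list()
    parts <- vapply(sort(names(data)), function(mime) {
      val <- collapse_source(data[[mime]])
      if (grepl("^image/", mime)) {
        raw <- tryCatch(jsonlite::base64_dec(gsub("\\s", "", val)),
                        error = function(e) charToRaw(val))
        val <- rlang::hash(raw)
      }
      paste0(mime, ":", val)
    }, character(1))
    txt <- paste(parts, collapse = "\n")
  } else if (identical(type, "error")) {
    txt <- paste0(output$ename %||% "", ": ", output$evalue %||% "")
  } else {
    txt <- ""
  }
  txt <- gsub("\033\\[[0-9;]*[A-Za-z]", "", txt)        # ANSI escapes
  lines <- split_lines(txt)
  lines <- sub("[ \t]+$", "", lines)                     # trailing whitespace
  txt <- paste(lines, collapse = "\n")
  if (mask_transients) {
    txt <- gsub("0x[0-9a-fA-F]+", "0xADDR", txt)
    txt <- gsub("\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}:\\d{2}[0-9.:+Z-]*",
                "TIMESTAMP", txt)
  }
  txt
}

cell_output_text <- function(cell, mask_transients = FALSE) {
  outs <- cell$outputs %||% list()
  paste(vapply(outs, normalize_output, character(1),
               mask_transients = mask_transients), collapse = "\n---\n")
}

#' Diff a re-executed notebook against the original
#'
#' Compares, per code cell, the stored outputs with the re-executed ones
#' after normalization (ANSI escapes stripped, trailing whitespace ignored;
#' transient-token masking of object addresses and timestamps is off by
#' default). Execution-count mismatches are tallied separately, as are files
#' created or modified under the notebook directory (from the workspace
#' manifests).
#'
#' @param original_doc,executed_doc Parsed notebook documents with identical
#'   cell counts and order.
#' @param workspace_before,workspace_after Manifests from
#'   [snapshot_workspace()].
#' @param mask_transients Mask hexadecimal object addresses and ISO
#'   timestamps before comparison.
#' @return A list of class `diff_report` with `output_diff_count`,
#'   `execcount_diff_count`, `file_diff_count`, and a `per_cell` data.frame
#'   (`cell_index`, `kind`, `summary`).
#' @export
diff_against_original <- function(original_doc, executed_doc,
                                  workspace_before = NULL,
                                  workspace_after = NULL,
                                  mask_transients = FALSE) {
  orig_cells <- original_doc$cells %||% list()
  exec_cells <- executed_doc$cells %||% list()
  stopifnot(length(orig_cells) == length(exec_cells))
  per_cell <- list()
  out_diffs <- 0L; count_diffs <- 0L
  for (i in seq_along(orig_cells)) {
    oc <- orig_cells[[i]]; ec <- exec_cells[[i]]
    stopifnot(identical(oc$cell_type, ec$cell_type))
    if (!identical(oc$cell_type, "code")) next
    o_txt <- cell_output_text(oc, mask_transients)
    e_txt <- cell_output_text(ec, mask_transients)
    if (!identical(o_txt, e_txt)) {
      out_diffs <- out_diffs + 1L
      per_cell[[length(per_cell) + 1L]] <- data.frame(
        cell_index = i - 1L, kind = "output",
        summary = sprintf("stored %d chars, re-executed %d chars",
                          nchar(o_txt), nchar(e_txt)),
        stringsAsFactors = FALSE)
    }
    o_ec <- oc$execution_count; e_ec <- ec$execution_count
    o_ec <- if (is.null(o_ec)) NA_real_ else suppressWarnings(as.numeric(o_ec))
    e_ec <- if (is.null(e_ec)) NA_real_ else suppressWarnings(as.numeric(e_ec))
    if (!identical(is.na(o_ec), is.na(e_ec)) ||
        (!is.na(o_ec) && !is.na(e_ec) && o_ec != e_ec)) {
      count_diffs <- count_diffs + 1L
      per_cell[[length(per_cell) + 1L]] <- data.frame(
        cell_index = i - 1L, kind = "execution_count",
        summary = sprintf("stored %s, re-executed %s", o_ec, e_ec),
        stringsAsFactors = FALSE)
    }
  }
  file_diffs <- 0L
  if (!is.null(workspace_before) && !is.null(workspace_after)) {
    merged <- merge(workspace_before, workspace_after, by = "path",
                    all = TRUE, suffixes = c("_before", "_after"))
    changed <- is.na(merged$md5_before) | is.na(merged$md5_after) |
      merged$md5_before != merged$md5_after
    file_diffs <- sum(changed)
    for (p in merged$path[changed]) {
      per_cell[[length(per_cell) + 1L]] <- data.frame(
        cell_index = NA_integer_, kind = "file",
        summary = paste0("workspace file changed: ", p),
        stringsAsFactors = FALSE)
    }
  }
  per_cell_df <- if (length(per_cell)) do.call(rbind, per_cell) else
    data.frame(cell_index = integer(0), kind = character(0),
               summary = character(0), stringsAsFactors = FALSE)
  base::structure(list(
    output_diff_count = out_diffs,
    execcount_diff_count = count_diffs,
    file_diff_count = as.integer(file_diffs),
    per_cell = per_cell_df
  ), class = "diff_report")
}

OUTCOME_LABELS <- c("repo_unavailable", "not_target_language",
                    "no_declared_pipeline_entry", "install_failed",
                    "exception", "timeout", "excluded",
                    "finished_different", "finished_identical")

#' Classify the pipeline outcome for one notebook
#'
#' Total function over consistent pipeline prefixes, with fixed precedence:
#' unavailable repository, then non-target language, then install failure,
#' then timeout / kernel-start exclusion, then first exception, then finished
#' with identical or different results. By default `finished_identical`
#' requires zero output-content differences; execution-count and workspace
#' file differences are recorded but excluded from the label unless
#' `strict_counters = TRUE`.
#'
#' @param repo A `repository_record` (or list with `available`).
#' @param structure A `notebook_structure`, or `NULL` when the document never
#'   parsed (classified `no_declared_pipeline_entry`).
#' @param install An `install_outcome`, or `NULL` when never attempted.
#' @param trace An `execution_trace`, or `NULL` (required when install
#'   succeeded).
#' @param diff A `diff_report`, or `NULL` (required when execution
#'   completed).
#' @param strict_counters Also require identical execution counts and an
#'   unchanged workspace for the `finished_identical` label.
#' @param target_language Kernel language the pipeline executes.
#' @return A list of class `outcome_class` with `label` and
#'   `exception_type` (present iff `label == "exception"`).
#' @export
classify_outcome <- function(repo, structure, install = NULL, trace = NULL,
                             diff = NULL, strict_counters = FALSE,
                             target_language = "python") {
  lab <- function(label, exception_type = NA_character_) {
    stopifnot(label %in% OUTCOME_LABELS)
    base::structure(list(label = label, exception_type = exception_type),
                    class = "outcome_class")
  }
  if (!isTRUE(repo$available)) return(lab("repo_unavailable"))
  if (is.null(structure)) return(lab("no_declared_pipeline_entry"))
  if (!identical(structure$language, target_language)) {
    return(lab("not_target_language"))
  }
  if (is.null(install)) return(lab("no_declared_pipeline_entry"))
  if (!isTRUE(install$success)) {
    if (!is.null(trace)) {
      stop("inconsistent pipeline prefix: execution trace present after install failure",
           call. = FALSE)
    }
    return(lab("install_failed"))
  }
  if (is.null(trace)) {
    stop("inconsistent pipeline prefix: environment handed off but no execution trace",
         call. = FALSE)
  }
  if (isTRUE(trace$timed_out)) return(lab("timeout"))
  if (isTRUE(trace$kernel_start_failed)) return(lab("excluded"))
  if (!is.na(trace$first_exception_type)) {
    return(lab("exception", canonical_exception(trace$first_exception_type)))
  }
  if (is.null(diff)) {
    stop("inconsistent pipeline prefix: completed execution but no diff report",
         call. = FALSE)
  }
  identical_run <- diff$output_diff_count == 0L &&
    (!strict_counters ||
       (diff$execcount_diff_count == 0L && diff$file_diff_count == 0L))
  lab(if (identical_run) "finished_identical" else "finished_different")
}
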
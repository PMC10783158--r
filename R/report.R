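# Corpus-level reporting: printed-style percentages, the reproducibility
# ratio, grouped summary tables, and the finished-group comparison.

round_half_away <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Render a percentage the way corpus reports print it
#'
#' `100 * numerator / denominator`, rounded half away from zero at the
#' requested number of digits, rendered as a stable decimal string (so
#' `percentage(1203, 15817, 2)` is `"7.61"`).
#'
#' @param numerator,denominator Counts; a zero denominator yields the
#'   explicit undefined value `NA_character_`, never a division error.
#' @param digits Decimal digits to print.
#' @return A decimal string, or `NA_character_` when undefined.
#' @export
percentage <- function(numerator, denominator, digits = 2) {
  if (is.na(denominator) || denominator == 0) return(NA_character_)
  value <- round_half_away(100 * numerator / denominator, digits)
  formatC(value, format = "f", digits = digits)
}

#' Reproducibility ratio of the finished notebooks
#'
#' `different / (different + identical)`: the probability that a notebook
#' which ran through produced results differing from the stored ones.
#'
#' @param different,identical Counts of finished notebooks per group.
#' @return A list with `value` (full precision) and `display` (rounded to 2
#'   decimals); both `NA` when the two counts are zero.
#' @export
repro_ratio <- function(different, identical) {
  total <- different + identical
  if (is.na(total) || total == 0) {
    return(list(value = NA_real_, display = NA_real_))
  }
  value <- different / total
  list(value = value, display = round_half_away(value, 2))
}

SUMMARY_DIMENSIONS <- c("year", "journal", "mesh_top_level", "language",
                        "interpreter_version", "exception_type", "style_code",
                        "article_type")

#' Grouped summary table over the corpus
#'
#' Counts per key of the requested dimension, ordered by descending count
#' (ties lexicographic), with an optional normalized column. The denominator
#' rule used is recorded verbatim in the result.
#'
#' @param store A [corpus_store()].
#' @param dimension One of `year`, `journal`, `mesh_top_level`, `language`,
#'   `interpreter_version`, `exception_type`, `style_code`, `article_type`.
#' @param normalizer Optional: `"notebooks"` divides each count by the number
#'   of notebooks carrying the same key (e.g. exceptions per year normalized
#'   by notebooks published that year).
#' @return A list of class `summary_table` with `dimension`, `rows`
#'   (data.frame `key`, `count`, optionally `normalized`), and
#'   `denominator_definition`.
#' @export
summarize_corpus <- function(store, dimension, normalizer = NULL) {
  if (!dimension %in% SUMMARY_DIMENSIONS) {
    stop("unknown summary dimension: ", dimension, call. = FALSE)
  }
  profiles <- store_table(store, "profiles")
  outcomes <- store_table(store, "outcomes")
  articles <- store_table(store, "articles")

  keys <- switch(dimension,
    language = profiles$language,
    interpreter_version = {
      v <- profiles$language_version_full
      ifelse(is.na(v), "undeclared", sub("^([0-9]+\\.[0-9]+).*$", "\\1", v))
    },
    exception_type = {
      exc <- outcomes[outcomes$label == "exception", , drop = FALSE]
      exc$exception_type
    },
    style_code = store_table(store, "style_findings")$code,
    year = {
      d <- articles$date_published
      substr(d[!is.na(d)], 1, 4)
    },
    journal = articles$journal_id,
    article_type = articles$article_type,
    mesh_top_level = store_table(store, "article_mesh")$top_level
  )
  keys <- keys[!is.na(keys)]
  if (length(keys) == 0L) {
    rows <- data.frame(key = character(0), count = integer(0),
                       stringsAsFactors = FALSE)
  } else {
    tab <- table(keys)
    rows <- data.frame(key = names(tab), count = as.integer(tab),
                       stringsAsFactors = FALSE)
    rows <- rows[order(-rows$count, rows$key, method = "radix"), , drop = FALSE]
    rownames(rows) <- NULL
  }
  denom_def <- "raw counts; denominator is the number of records carrying the dimension"
  if (identical(normalizer, "notebooks") && nrow(rows) > 0L) {
    denom_def <- "count divided by the number of notebooks sharing the key"
    nb_per_key <- notebooks_per_key(store, dimension)
    rows$normalized <- rows$count / nb_per_key[rows$key]
  }
  base::structure(list(dimension = dimension, rows = rows,
                       denominator_definition = denom_def),
                  class = "summary_table")
}

# notebooks per dimension key, used as the normalizing denominator
notebooks_per_key <- function(store, dimension) {
  profiles <- store_table(store, "profiles")
  if (nrow(profiles) == 0L) return(c())
  key <- switch(dimension,
    language = profiles$language,
    interpreter_version = ifelse(is.na(profiles$language_version_full), "undeclared",
                                 sub("^([0-9]+\\.[0-9]+).*$", "\\1",
                                     profiles$language_version_full)),
    stop("normalization by notebooks is not defined for dimension ", dimension,
         call. = FALSE)
  )
  tab <- table(key)
  setNames(as.numeric(tab), names(tab))
}

#' Compare the finished-different and finished-identical groups
#'
#' Per-group means of the notebook-level features (cells by type, the
#' Markdown:code ratio, recorded differences, execution time) for the
#' notebooks that ran through. Execution time per code cell is reported both
#' as the ratio of the group means and as the mean of per-notebook ratios —
#' the two estimators differ and neither is adjudicated. Group sizes always
#' equal the corresponding [flow_counts()] entries; an empty group's means
#' are `NA`.
#'
#' @param store A [corpus_store()].
#' @return A data.frame of class `group_comparison`, one row per group.
#' @export
compare_groups <- function(store) {
  outcomes <- store_table(store, "outcomes")
  profiles <- store_table(store, "profiles")
  execs <- store_table(store, "executions")
  diffs <- store_table(store, "diffs")
  repos <- store_table(store, "repositories")

  groups <- list(different = "finished_different", identical = "finished_identical")
  rows <- lapply(names(groups), function(g) {
    sel <- outcomes[outcomes$label == groups[[g]], , drop = FALSE]
    n <- nrow(sel)
    if (n == 0L) {
      return(data.frame(group = g, notebooks = 0L, setup_py = NA_integer_,
                        requirements_txt = NA_integer_, pipfile = NA_integer_,
                        mean_total_cells = NA_real_, mean_code_cells = NA_real_,
                        mean_markdown_cells = NA_real_, mean_empty_cells = NA_real_,
                        mean_md_code_ratio = NA_real_, mean_differences = NA_real_,
                        mean_exec_time = NA_real_,
                        time_per_code_cell_ratio_of_means = NA_real_,
                        time_per_code_cell_mean_of_ratios = NA_real_,
                        stringsAsFactors = FALSE))
    }
    key <- paste(sel$repo_url, sel$relative_path)
    p <- profiles[paste(profiles$repo_url, profiles$relative_path) %in% key, , drop = FALSE]
    e <- execs[paste(execs$repo_url, execs$relative_path) %in% key, , drop = FALSE]
    d <- diffs[paste(diffs$repo_url, diffs$relative_path) %in% key, , drop = FALSE]
    # one row per notebook (declaration counts are per notebook, via its repo)
    r <- repos[match(sel$repo_url, repos$canonical_url), , drop = FALSE]
    md_ratio <- ifelse(p$code_cells > 0, p$markdown_cells / p$code_cells, 0)
    per_cell_ratio <- {
      m <- merge(e[, c("repo_url", "relative_path", "duration")],
                 p[, c("repo_url", "relative_path", "code_cells")],
                 by = c("repo_url", "relative_path"))
      ok <- m$code_cells > 0
      if (any(ok)) mean(m$duration[ok] / m$code_cells[ok]) else NA_real_
    }
    total_diffs <- if (nrow(d)) d$output_diff_count + d$execcount_diff_count +
      d$file_diff_count else numeric(0)
    data.frame(
      group = g, notebooks = n,
      setup_py = sum(r$has_setup %||% logical(0), na.rm = TRUE),
      requirements_txt = sum(r$has_requirements %||% logical(0), na.rm = TRUE),
      pipfile = sum(r$has_pipfile %||% logical(0), na.rm = TRUE),
      mean_total_cells = mean(p$cells_total),
      mean_code_cells = mean(p$code_cells),
      mean_markdown_cells = mean(p$markdown_cells),
      mean_empty_cells = mean(p$empty_cells),
      mean_md_code_ratio = mean(md_ratio),
      mean_differences = if (length(total_diffs)) mean(total_diffs) else NA_real_,
      mean_exec_time = mean(e$duration),
      time_per_code_cell_ratio_of_means = mean(e$duration) / mean(p$code_cells),
      time_per_code_cell_mean_of_ratios = per_cell_ratio,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  fc <- flow_counts(store)
  stopifnot(out$notebooks[out$group == "different"] == fc$finished_different,
            out$notebooks[out$group == "identical"] == fc$finished_identical)
  class(out) <- c("group_comparison", class(out))
  out
}
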
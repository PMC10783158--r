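# Literature mining: JATS full-text parsing, repository-link extraction and
# normalization, MeSH top-level resolution.

GITHUB_HOST_PATTERN <- paste0(
  "(?:https?://)?(?:www\\.)?",
  "(?:github\\.com|gist\\.github\\.com|raw\\.githubusercontent\\.com|",
  "nbviewer\\.jupyter\\.org|nbviewer\\.org|[A-Za-z0-9-]+\\.github\\.io)",
  "[^\\s\"'<>\\)\\]]*"
)

#' Read a JATS article document
#'
#' @param path Path to a JATS XML file (one article per file, as served by
#'   full-text XML exports).
#' @return An `xml2` document. Malformed XML raises a parse error (with the
#'   offending position reported by the parser); a document whose root is not
#'   `<article>` raises a structural error.
#' @export
read_jats <- function(path) {
  doc <- xml2::read_xml(path)
  if (!identical(xml2::xml_name(xml2::xml_root(doc)), "article")) {
    stop("not a JATS document: root element is <",
         xml2::xml_name(xml2::xml_root(doc)), ">, expected <article>",
         call. = FALSE)
  }
  doc
}

jats_text1 <- function(doc, xpath) {
  node <- xml2::xml_find_first(doc, xpath)
  if (inherits(node, "xml_missing")) return(NA_character_)
  txt <- xml2::xml_text(node)
  if (!nzchar(trimws(txt))) NA_character_ else trimws(txt)
}

jats_date <- function(doc, xpath) {
  node <- xml2::xml_find_first(doc, xpath)
  if (inherits(node, "xml_missing")) return(NA_character_)
  y <- jats_text1(node, "./year")
  m <- jats_text1(node, "./month")
  d <- jats_text1(node, "./day")
  if (is.na(y)) return(NA_character_)
  sprintf("%s-%02d-%02d", y,
          as.integer(if (is.na(m)) "1" else m),
          as.integer(if (is.na(d)) "1" else d))
}

#' Create a journal registry
#'
#' A registry deduplicates journals across articles: by ISSN when present,
#' else by (case-folded) title. Used by [extract_article_metadata()].
#'
#' @return An environment holding the registered journal records.
#' @export
journal_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$journals <- list()
  reg$index <- new.env(parent = emptyenv())
  reg
}

register_journal <- function(registry, journal) {
  stopifnot(!is.na(journal$issn) || !is.na(journal$title))
  key <- if (!is.na(journal$issn)) {
    paste0("issn:", tolower(journal$issn))
  } else {
    paste0("title:", tolower(journal$title))
  }
  existing <- get0(key, envir = registry$index, inherits = FALSE)
  if (!is.null(existing)) return(existing)
  id <- sprintf("J%03d", length(registry$journals) + 1L)
  journal$journal_id <- id
  registry$journals[[id]] <- journal
  assign(key, id, envir = registry$index)
  id
}

#' List the journals registered so far
#' @param registry A [journal_registry()].
#' @return A data.frame with one row per distinct journal.
#' @export
registry_journals <- function(registry) {
  if (length(registry$journals) == 0L) {
    return(data.frame(journal_id = character(0), issn = character(0),
                      title = character(0), nlm_abbrev = character(0),
                      iso_abbrev = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(registry$journals, function(j) {
    data.frame(journal_id = j$journal_id, issn = j$issn, title = j$title,
               nlm_abbrev = j$nlm_abbrev, iso_abbrev = j$iso_abbrev,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Extract article metadata from a JATS document
#'
#' Pulls out the identifiers, title, dates, license, keywords, MeSH subject
#' descriptors, authors, and every repository mention. Fields absent from the
#' XML are reported as `NA`, never invented. The article's journal is
#' registered (and deduplicated) in `registry`.
#'
#' @param doc A JATS document from [read_jats()].
#' @param registry A [journal_registry()].
#' @return A list of class `article_record` with fields `pmc_id`, `pubmed_id`,
#'   `doi`, `title`, `journal_id`, `publisher_id`, `publisher_name`, dates,
#'   `license_text`, `copyright_text`, `article_type`, `keywords`,
#'   `mesh_terms`, `authors` (data.frame), `repo_mentions` (data.frame of raw
#'   link strings with their enclosing region), and `repo_links` (the accepted
#'   normalized links).
#' @export
extract_article_metadata <- function(doc, registry = journal_registry()) {
  pmc_id <- jats_text1(doc, "//front//article-meta/article-id[@pub-id-type='pmc']")
  if (is.na(pmc_id)) stop("article has no PMC identifier", call. = FALSE)

  journal <- list(
    issn = jats_text1(doc, "//front//journal-meta/issn"),
    title = jats_text1(doc, "//front//journal-meta//journal-title"),
    nlm_abbrev = jats_text1(
      doc, "//front//journal-meta/journal-id[@journal-id-type='nlm-ta']"),
    iso_abbrev = jats_text1(
      doc, "//front//journal-meta/journal-id[@journal-id-type='iso-abbrev']")
  )
  journal_id <- if (!is.na(journal$issn) || !is.na(journal$title)) {
    register_journal(registry, journal)
  } else {
    NA_character_
  }

  contribs <- xml2::xml_find_all(doc, "//front//contrib-group/contrib")
  authors <- if (length(contribs)) {
    do.call(rbind, lapply(contribs, function(node) {
      data.frame(
        surname = jats_text1(node, ".//surname"),
        given = jats_text1(node, ".//given-names"),
        orcid = jats_text1(node, ".//contrib-id[@contrib-id-type='orcid']"),
        email = jats_text1(node, ".//email"),
        stringsAsFactors = FALSE
      )
    }))
  } else {
    data.frame(surname = character(0), given = character(0),
               orcid = character(0), email = character(0),
               stringsAsFactors = FALSE)
  }

  keywords <- xml2::xml_text(xml2::xml_find_all(doc, "//front//kwd-group/kwd"))
  mesh_terms <- xml2::xml_text(xml2::xml_find_all(
    doc, "//front//article-categories/subj-group[@subj-group-type='mesh']/subject"))

  mentions <- extract_repo_mentions(doc)
  normalized <- lapply(mentions$raw, normalize_repo_link)
  accepted <- Filter(function(x) inherits(x, "nb_repo_link"), normalized)
  rejected <- Filter(function(x) inherits(x, "nb_link_rejection"), normalized)

  record <- list(
    pmc_id = pmc_id,
    pubmed_id = jats_text1(doc, "//front//article-meta/article-id[@pub-id-type='pmid']"),
    doi = jats_text1(doc, "//front//article-meta/article-id[@pub-id-type='doi']"),
    title = jats_text1(doc, "//front//article-meta//article-title"),
    journal_id = journal_id,
    publisher_id = jats_text1(doc, "//front//article-meta/article-id[@pub-id-type='publisher-id']"),
    publisher_name = jats_text1(doc, "//front//journal-meta//publisher-name"),
    article_type = scalar_or_na(xml2::xml_attr(xml2::xml_root(doc), "article-type")),
    date_received = jats_date(doc, "//front//article-meta/history/date[@date-type='received']"),
    date_accepted = jats_date(doc, "//front//article-meta/history/date[@date-type='accepted']"),
    date_published = jats_date(doc, "//front//article-meta/pub-date"),
    license_text = jats_text1(doc, "//front//permissions/license"),
    copyright_text = jats_text1(doc, "//front//permissions/copyright-statement"),
    keywords = keywords,
    mesh_terms = mesh_terms,
    authors = authors,
    repo_mentions = mentions,
    repo_links = accepted,
    link_rejections = rejected
  )
  if (!is.na(record$date_received) && !is.na(record$date_published) &&
      as.Date(record$date_published) < as.Date(record$date_received)) {
    stop("article ", pmc_id, ": published date earlier than received date",
         call. = FALSE)
  }
  structure(record, class = "article_record")
}

#' Extract raw repository-link mentions from a JATS document
#'
#' Scans the abstract, body, and back matter (data availability, supplementary
#' material, references) for candidate repository URLs, in document order,
#' preserving duplicates. Both `<ext-link>` href attributes and plain-text
#' URLs are caught; the enclosing region is recorded so either inclusion
#' policy (with or without back matter) can be replayed downstream.
#'
#' @param doc A JATS document.
#' @return A data.frame with columns `raw` and `section`.
#' @export
extract_repo_mentions <- function(doc) {
  regions <- list(
    abstract = "//front//abstract",
    body = "//body",
    back = "//back"
  )
  rows <- list()
  for (region in names(regions)) {
    nodes <- xml2::xml_find_all(doc, regions[[region]])
    for (node in nodes) {
      serialized <- as.character(node)
      matches <- regmatches(serialized,
                            gregexpr(GITHUB_HOST_PATTERN, serialized, perl = TRUE))[[1]]
      for (m in matches) {
        raw <- sub("[.,;:]+$", "", m)
        raw <- gsub("&amp;", "&", raw, fixed = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          raw = raw, section = region, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(raw = character(0), section = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

new_repo_link <- function(owner, repo, source_form) {
  structure(list(
    owner = owner,
    repo_name = repo,
    canonical_url = paste0("https://github.com/", owner, "/", repo),
    source_form = source_form
  ), class = "nb_repo_link")
}

new_link_rejection <- function(raw, reason) {
  stopifnot(reason %in% c("owner_only", "pages_site", "malformed", "non_repo_host"))
  structure(list(raw_text = raw, reason = reason), class = "nb_link_rejection")
}

valid_path_segment <- function(x) {
  nzchar(x) && grepl("^[A-Za-z0-9_.-]+$", x) && !identical(x, ".") && !identical(x, "..")
}

#' Normalize a raw repository link
#'
#' Reduces the many dialects in which repositories are cited (file `blob`
#' and `tree` paths, nbviewer wrappers, raw-content hosts, trailing `.git`,
#' scheme-less forms, fragments, trailing slashes) to the canonical
#' `https://github.com/{owner}/{repo}` form. Owner-only links, user pages
#' (`*.github.io`), and gists are classified as rejections, which are values,
#' not errors. Deterministic, and idempotent on the canonical URL.
#'
#' @param raw A nonempty link string.
#' @return An object of class `nb_repo_link` (fields `owner`, `repo_name`,
#'   `canonical_url`, `source_form`) or `nb_link_rejection` (fields
#'   `raw_text`, `reason`).
#' @export
normalize_repo_link <- function(raw) {
  stopifnot(is_string(raw), nzchar(raw))
  url <- trimws(raw)
  url <- sub("[.,;:]+$", "", url)
  url <- sub("#.*$", "", url)
  url <- sub("\\?.*$", "", url)
  url <- sub("^https?://", "", url, ignore.case = TRUE)
  url <- sub("^www\\.", "", url, ignore.case = TRUE)
  url <- sub("/+$", "", url)

  parts <- strsplit(url, "/", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) return(new_link_rejection(raw, "malformed"))
  host <- tolower(parts[[1]])
  path <- parts[-1]

  if (identical(host, "gist.github.com")) {
    return(new_link_rejection(raw, "non_repo_host"))
  }
  if (grepl("^[a-z0-9-]+\\.github\\.io$", host)) {
    return(new_link_rejection(raw, "pages_site"))
  }
  if (host %in% c("nbviewer.jupyter.org", "nbviewer.org")) {
    # nbviewer wraps the target: /github/{owner}/{repo}/...
    if (length(path) >= 3L && identical(tolower(path[[1]]), "github")) {
      owner <- path[[2]]; repo <- strip_git_suffix(path[[3]])
      if (valid_path_segment(owner) && valid_path_segment(repo)) {
        return(new_repo_link(owner, repo, "nbviewer"))
      }
    }
    return(new_link_rejection(raw, "malformed"))
  }
  if (identical(host, "raw.githubusercontent.com")) {
    if (length(path) >= 2L) {
      owner <- path[[1]]; repo <- strip_git_suffix(path[[2]])
      if (valid_path_segment(owner) && valid_path_segment(repo)) {
        return(new_repo_link(owner, repo, "raw_host"))
      }
    }
    return(new_link_rejection(raw, "malformed"))
  }
  if (identical(host, "github.com")) {
    if (length(path) == 0L) return(new_link_rejection(raw, "malformed"))
    if (length(path) == 1L) {
      if (valid_path_segment(path[[1]])) {
        return(new_link_rejection(raw, "owner_only"))
      }
      return(new_link_rejection(raw, "malformed"))
    }
    owner <- path[[1]]
    repo_raw <- path[[2]]
    repo <- strip_git_suffix(repo_raw)
    if (!valid_path_segment(owner) || !valid_path_segment(repo)) {
      return(new_link_rejection(raw, "malformed"))
    }
    form <- if (!identical(repo, repo_raw)) {
      "git_suffix"
    } else if (length(path) == 2L) {
      "plain"
    } else if (identical(path[[3]], "blob")) {
      "blob_path"
    } else if (identical(path[[3]], "tree")) {
      "tree_path"
    } else {
      "other"
    }
    return(new_repo_link(owner, repo, form))
  }
  new_link_rejection(raw, "non_repo_host")
}

strip_git_suffix <- function(x) sub("\\.git$", "", x)

#' Load a MeSH descriptor-to-top-level lookup table
#'
#' Reads a two-column TSV (`descriptor`, `top_level`) and returns a lookup
#' function mapping each descriptor to its top-level ancestor. Descriptors
#' absent from the table map to `"unknown"`. A small synthetic table for
#' offline use ships with the package under
#' `inst/extdata/mesh_tree_synthetic.tsv`; a service-backed adapter can
#' implement the same single-argument interface.
#'
#' @param path TSV file; defaults to the bundled synthetic table.
#' @return A function `descriptor -> top-level descriptor`.
#' @export
load_mesh_lookup <- function(path = system.file("extdata", "mesh_tree_synthetic.tsv",
                                                package = "nbaudit")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("descriptor", "top_level") %in% names(tab)))
  map <- setNames(tab$top_level, tab$descriptor)
  function(term) {
    if (term %in% names(map)) unname(map[[term]]) else "unknown"
  }
}

#' Resolve MeSH descriptors to their top-level ancestors
#'
#' @param terms Character vector of MeSH descriptor strings.
#' @param tree_lookup Function mapping a descriptor to its top-level ancestor
#'   (see [load_mesh_lookup()]); must return `"unknown"` for unmapped terms.
#' @return Deduplicated character vector of top-level descriptors, ordered by
#'   first occurrence. A term that is itself top-level maps to itself.
#' @export
resolve_top_level_mesh <- function(terms, tree_lookup) {
  if (length(terms) == 0L) return(character(0))
  tops <- vapply(terms, tree_lookup, character(1), USE.NAMES = FALSE)
  unique(tops)
}
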
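# Literature mining: link normalization, JATS extraction, MeSH resolution.

test_that("repository links in every recognized dialect normalize to the canonical template", {
  cases <- link_dialect_cases()
  for (i in seq_len(nrow(cases))) {
    res <- normalize_repo_link(cases$raw[i])
    if (is.na(cases$canonical[i])) {
      expect_s3_class(res, "nb_link_rejection")
      expect_identical(res$reason, cases$form[i], label = cases$raw[i])
    } else {
      expect_s3_class(res, "nb_repo_link")
      expect_identical(res$canonical_url, cases$canonical[i], label = cases$raw[i])
      expect_identical(res$source_form, cases$form[i], label = cases$raw[i])
      expect_false(grepl("/", res$owner, fixed = TRUE))
      expect_false(grepl("/", res$repo_name, fixed = TRUE))
    }
  }
})

test_that("normalization is idempotent on the canonical URL", {
  cases <- link_dialect_cases()
  for (raw in cases$raw[!is.na(cases$canonical)]) {
    once <- normalize_repo_link(raw)
    twice <- normalize_repo_link(once$canonical_url)
    expect_s3_class(twice, "nb_repo_link")
    expect_identical(twice$canonical_url, once$canonical_url)
  }
})

test_that("owner and repository casing is preserved as written", {
  res <- normalize_repo_link("https://GitHub.com/MyLab/MyRepo")
  expect_identical(res$owner, "MyLab")
  expect_identical(res$repo_name, "MyRepo")
})

test_that("a minimal article yields only the fields present, never invented ones", {
  dir <- tempfile(); forged <- forge_article(list(pmc_id = "PMC1", title = "Tiny"), dir)
  rec <- extract_article_metadata(read_jats(forged$path))
  expect_identical(rec$pmc_id, "PMC1")
  expect_identical(rec$title, "Tiny")
  expect_true(is.na(rec$doi))
  expect_true(is.na(rec$pubmed_id))
  expect_true(is.na(rec$date_published))
  expect_true(is.na(rec$license_text))
  expect_length(rec$mesh_terms, 0)
  expect_identical(nrow(rec$repo_mentions), 0L)
})

test_that("forged articles are recovered field-for-field and link-for-link", {
  dir <- tempfile()
  spec <- list(
    pmc_id = "PMC42", title = "A forged study", doi = "10.1000/x42",
    pubmed_id = "990042",
    journal = list(issn = "1234-5678", title = "Forged Letters"),
    article_type = "research-article",
    date_received = "2020-01-10", date_published = "2020-06-01",
    license = "CC BY 4.0", keywords = c("k1", "k2"),
    mesh = c("Genomics", "Neoplasms"),
    authors = list(list(surname = "Doe", given = "Jo", orcid = "0000-0000-0000-0000")),
    links = list(
      list(dialect = "plain", owner = "o1", repo = "r1",
           section = "abstract", encoding = "ext-link"),
      list(dialect = "plain", owner = "o1", repo = "r1",
           section = "back", encoding = "text"),
      list(dialect = "nbviewer", owner = "o2", repo = "r2",
           section = "body", encoding = "text"),
      list(dialect = "owner_only", owner = "o3", repo = "r3",
           section = "body", encoding = "text")))
  forged <- forge_article(spec, dir)
  rec <- extract_article_metadata(read_jats(forged$path))
  expect_identical(rec$doi, "10.1000/x42")
  expect_identical(rec$article_type, "research-article")
  expect_identical(rec$date_published, "2020-06-01")
  expect_identical(rec$keywords, c("k1", "k2"))
  expect_identical(rec$mesh_terms, c("Genomics", "Neoplasms"))
  expect_identical(rec$authors$orcid, "0000-0000-0000-0000")
  # duplicates preserved; mentions recovered in document order
  # (abstract, then body, then back matter), both encodings caught
  expect_identical(sort(rec$repo_mentions$raw), sort(forged$links$raw))
  expect_identical(rec$repo_mentions$section,
                   c("abstract", "body", "body", "back"))
  canon <- vapply(rec$repo_links, `[[`, character(1), "canonical_url")
  expect_identical(sort(canon),
                   c("https://github.com/o1/r1", "https://github.com/o1/r1",
                     "https://github.com/o2/r2"))
  expect_identical(rec$link_rejections[[1]]$reason, "owner_only")
})

test_that("published-before-received dates are rejected as inconsistent", {
  dir <- tempfile()
  forged <- forge_article(list(pmc_id = "PMC9", title = "Backwards",
                               date_received = "2021-06-01",
                               date_accepted = "2021-06-10",
                               date_published = "2021-01-01"), dir)
  expect_error(extract_article_metadata(read_jats(forged$path)),
               "earlier than received")
})

test_that("journals are deduplicated by ISSN across articles", {
  dir <- tempfile()
  reg <- journal_registry()
  j <- list(issn = "9999-0000", title = "Shared Journal")
  a1 <- forge_article(list(pmc_id = "PMCa", title = "One", journal = j), dir)
  a2 <- forge_article(list(pmc_id = "PMCb", title = "Two",
                           journal = list(issn = "9999-0000",
                                          title = "Shared Journal (variant)")), dir)
  r1 <- extract_article_metadata(read_jats(a1$path), reg)
  r2 <- extract_article_metadata(read_jats(a2$path), reg)
  expect_identical(r1$journal_id, r2$journal_id)
  expect_identical(nrow(registry_journals(reg)), 1L)
})

test_that("malformed and non-JATS XML raise parse/structural errors", {
  bad <- tempfile(fileext = ".xml")
  writeLines("<article><unclosed></article>", bad)
  expect_error(read_jats(bad))
  notjats <- tempfile(fileext = ".xml")
  writeLines("<record><id>1</id></record>", notjats)
  expect_error(read_jats(notjats), "expected <article>")
})

test_that("an article without repository mentions yields an empty list", {
  dir <- tempfile()
  forged <- forge_article(list(pmc_id = "PMC7", title = "No code here"), dir)
  expect_identical(nrow(extract_repo_mentions(read_jats(forged$path))), 0L)
})

test_that("MeSH terms resolve to top-level ancestors, matching a brute-force walk", {
  # small parent-edge tree; the oracle walks edges to the root
  edges <- c(Genomics = "Biological Science Disciplines",
             "Sequence Analysis" = "Genomics",
             "Biological Science Disciplines" = "Biological Science Disciplines",
             Neoplasms = "Diseases", Diseases = "Diseases")
  brute_top <- function(term) {
    seen <- character(0)
    while (!term %in% seen) {
      seen <- c(seen, term)
      if (!term %in% names(edges)) return("unknown")
      nxt <- unname(edges[[term]])
      if (identical(nxt, term)) return(term)
      term <- nxt
    }
    term
  }
  lookup <- function(term) brute_top(term)
  # a top-level term maps to itself
  expect_identical(resolve_top_level_mesh("Diseases", lookup), "Diseases")
  # two terms sharing one ancestor collapse to a single entry
  expect_identical(
    resolve_top_level_mesh(c("Genomics", "Sequence Analysis"), lookup),
    "Biological Science Disciplines")
  # unmapped terms yield the sentinel
  expect_identical(resolve_top_level_mesh("Astrology", lookup), "unknown")
  # stable order by first occurrence, deduplicated
  expect_identical(
    resolve_top_level_mesh(c("Neoplasms", "Genomics", "Diseases"), lookup),
    c("Diseases", "Biological Science Disciplines"))
})

test_that("the bundled synthetic MeSH table drives the same interface", {
  lookup <- load_mesh_lookup()
  expect_identical(lookup("Genomics"), "Biological Science Disciplines")
  expect_identical(lookup("not-a-descriptor"), "unknown")
})
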
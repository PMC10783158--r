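# The synthetic-corpus forge: determinism, label coverage, engineered
# behaviors.

test_that("the default corpus covers every behavior label at least twice", {
  audit <- shared_audit()
  hist <- table(audit$manifest$notebooks$behavior)
  labels <- c("clean_identical", "clean_different", "exc_ModuleNotFoundError",
              "exc_FileNotFoundError", "exc_ImportError", "exc_NameError",
              "exc_IOError", "exc_AttributeError", "exc_ValueError",
              "exc_TypeError", "exc_KeyError", "timeout", "non_target_kernel",
              "unknown_language", "install_fail")
  for (label in labels) {
    expect_gte(hist[[label]], 2L)
  }
})

test_that("forging with a fixed seed is deterministic, and seeds matter", {
  s1 <- forge_notebook("clean_identical",
                       structure = list(code = 2L, markdown = 1L, title = "D"),
                       seed = 3L)
  s2 <- forge_notebook("clean_identical",
                       structure = list(code = 2L, markdown = 1L, title = "D"),
                       seed = 3L)
  s3 <- forge_notebook("clean_identical",
                       structure = list(code = 2L, markdown = 1L, title = "D"),
                       seed = 4L)
  expect_identical(s1$doc, s2$doc)
  expect_false(identical(s1$doc, s3$doc))
})

test_that("each engineered exception fixture raises exactly its class", {
  for (behavior in c("exc_KeyError", "exc_ValueError", "exc_AttributeError",
                     "exc_NameError", "exc_IOError")) {
    forged <- forge_notebook(behavior,
                             structure = list(code = 2L, markdown = 0L,
                                              title = behavior), seed = 9L)
    path <- tempfile(fileext = ".ipynb")
    write_notebook(forged$doc, path)
    trace <- execute_notebook(path, h_python_handle(), timeout = 30)
    expect_false(trace$completed)
    expect_identical(trace$first_exception_canonical, forged$expected_exception,
                     label = behavior)
  }
})

test_that("clean fixtures embed stored outputs from a real forge-time run", {
  dir <- tempfile()
  spec <- list(owner = "o", name = "clean", declarations = "requirements",
               installable = TRUE,
               notebooks = list(list(path = "a.ipynb",
                                     behavior = "clean_identical",
                                     structure = list(code = 3L, markdown = 1L,
                                                      title = "A"))))
  manifest <- forge_repository(spec, dir, seed = 2L)
  nb <- read_notebook(file.path(dir, "o", "clean", "a.ipynb"))
  code_cells <- Filter(function(c) identical(c$cell_type, "code"), nb$cells)
  expect_true(all(vapply(code_cells, function(c) length(c$outputs) > 0, logical(1))))
  # stored output text matches what the deterministic code prints
  trace <- execute_notebook(file.path(dir, "o", "clean", "a.ipynb"),
                            h_python_handle(), timeout = 30)
  rerun <- read_notebook(trace$executed_path)
  report <- diff_against_original(nb, rerun)
  expect_identical(report$output_diff_count, 0L)
})

test_that("manifest structure counts match the documents on disk", {
  audit <- shared_audit()
  nbs <- audit$manifest$notebooks
  labelled <- nbs[nbs$behavior != "raw_invalid_json", ]
  for (i in seq_len(nrow(labelled))) {
    rel <- sub("^https://github\\.com/", "", labelled$repo_url[i])
    path <- file.path(audit$workspace, "repos", rel, labelled$relative_path[i])
    s <- profile_structure(read_notebook(path))
    expect_identical(s$cells_total, labelled$cells_total[i], label = path)
    expect_identical(s$code_cells, labelled$code_cells[i], label = path)
    expect_identical(s$markdown_cells, labelled$markdown_cells[i], label = path)
  }
})

test_that("uninstallable repositories declare a requirement the index cannot resolve", {
  dir <- tempfile()
  spec <- list(owner = "o", name = "broken", declarations = "requirements",
               installable = FALSE,
               notebooks = list(list(path = "b.ipynb", behavior = "install_fail",
                                     structure = list(code = 2L, markdown = 0L,
                                                      title = "B"))))
  forge_repository(spec, dir, seed = 2L)
  index <- tempfile(); publish_local_index(index)
  root <- file.path(dir, "o", "broken")
  spec_env <- plan_environment(
    structure(list(language = "python", language_version_full = "3.11"),
              class = "notebook_structure"),
    detect_declarations(root), scope = "broken")
  out <- materialize_environment(spec_env, env_backend_local_index(index),
                                 tempfile(), root)
  expect_false(out$success)
})

test_that("repositories without declarations fall back to the distribution bundle", {
  dir <- tempfile()
  spec <- list(owner = "o", name = "bare", declarations = character(0),
               installable = TRUE,
               notebooks = list(list(path = "c.ipynb", behavior = "clean_identical",
                                     structure = list(code = 2L, markdown = 0L,
                                                      title = "C"))))
  forge_repository(spec, dir, seed = 2L)
  root <- file.path(dir, "o", "bare")
  plan <- plan_environment(
    structure(list(language = "python", language_version_full = "3.11"),
              class = "notebook_structure"),
    detect_declarations(root), scope = "bare")
  expect_identical(plan$dependency_source, "distribution_bundle")
})
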
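# Single-pass execution, output diffing, and outcome classification.

test_that("a clean notebook runs to completion, one pass, in document order", {
  nb <- h_notebook(list(
    h_cell("markdown", "# Clean"),
    h_cell("code", "x = 2"),
    h_cell("code", "y = x * 21"),
    h_cell("code", "print('answer', y)")))
  path <- h_write_nb(nb)
  trace <- execute_notebook(path, h_python_handle(), timeout = 30)
  expect_true(trace$completed)
  expect_false(trace$timed_out)
  expect_identical(trace$cells_executed, 3L)
  executed <- read_notebook(trace$executed_path)
  out <- executed$cells[[4]]$outputs[[1]]
  expect_identical(out$output_type, "stream")
  expect_identical(out$text, "answer 42\n")
  expect_identical(executed$cells[[4]]$execution_count, 3L)
})

test_that("execution stops at the first exception and records its class", {
  nb <- h_notebook(list(
    h_cell("code", "import nonexistent_module_zqx13"),
    h_cell("code", "print('never reached')")))
  trace <- execute_notebook(h_write_nb(nb), h_python_handle(), timeout = 30)
  expect_false(trace$completed)
  expect_identical(trace$first_exception_type, "ModuleNotFoundError")
  expect_identical(trace$first_exception_cell, 0L)
  expect_identical(trace$cells_executed, 1L)
})

test_that("IOError is reported under its canonical modern name", {
  nb <- h_notebook(list(h_cell("code", "raise IOError('synthetic')")))
  trace <- execute_notebook(h_write_nb(nb), h_python_handle(), timeout = 30)
  expect_identical(trace$first_exception_type, "OSError")
  expect_identical(trace$first_exception_canonical, "OSError")
  expect_identical(canonical_exception("IOError"), "OSError")
})

test_that("a wall-clock timeout aborts the run", {
  nb <- h_notebook(list(
    h_cell("code", "print('started')"),
    h_cell("code", "import time\ntime.sleep(30)\nprint('woke')")))
  trace <- execute_notebook(h_write_nb(nb), h_python_handle(), timeout = 2)
  expect_true(trace$timed_out)
  expect_false(trace$completed)
  expect_true(is.na(trace$first_exception_type))
})

test_that("magic and shell directives are stripped before execution", {
  nb <- h_notebook(list(
    h_cell("code", "%matplotlib inline\n!echo hi\nx = 1\nprint('x is', x)")))
  trace <- execute_notebook(h_write_nb(nb), h_python_handle(), timeout = 30)
  expect_true(trace$completed)
  executed <- read_notebook(trace$executed_path)
  expect_identical(executed$cells[[1]]$outputs[[1]]$text, "x is 1\n")
})

test_that("byte-identical documents diff to zero everywhere", {
  nb <- h_notebook(list(
    h_cell("code", "print(1)", outputs = list(h_stream("1\n")), ec = 1L),
    h_cell("markdown", "# t")))
  path <- h_write_nb(nb)
  doc <- read_notebook(path)
  report <- diff_against_original(doc, doc)
  expect_identical(report$output_diff_count, 0L)
  expect_identical(report$execcount_diff_count, 0L)
  expect_identical(report$file_diff_count, 0L)
})

test_that("stored outputs from an unseeded draw differ on re-execution", {
  forged <- forge_notebook("clean_different",
                           structure = list(code = 2L, markdown = 1L,
                                            title = "Draws"), seed = 5L)
  path <- tempfile(fileext = ".ipynb")
  write_notebook(forged$doc, path)
  original <- read_notebook(path)
  trace <- execute_notebook(path, h_python_handle(), timeout = 30)
  expect_true(trace$completed)
  report <- diff_against_original(original, read_notebook(trace$executed_path))
  expect_gte(report$output_diff_count, 1L)
})

test_that("re-executing a clean deterministic notebook twice yields no diff", {
  forged <- forge_notebook("clean_identical",
                           structure = list(code = 3L, markdown = 1L,
                                            title = "Stable"), seed = 5L)
  path <- tempfile(fileext = ".ipynb")
  write_notebook(forged$doc, path)
  t1 <- execute_notebook(path, h_python_handle(), timeout = 30)
  t2 <- execute_notebook(path, h_python_handle(), timeout = 30)
  report <- diff_against_original(read_notebook(t1$executed_path),
                                  read_notebook(t2$executed_path))
  expect_identical(report$output_diff_count, 0L)
  expect_identical(report$execcount_diff_count, 0L)
})

test_that("files created or modified by the run are tallied from manifests", {
  dir <- tempfile(); dir.create(dir)
  writeLines("old contents", file.path(dir, "result.csv"))
  nb <- h_notebook(list(h_cell(
    "code",
    "open('result.csv', 'w').write('new contents')\nopen('fresh.txt', 'w').write('x')")))
  path <- file.path(dir, "writer.ipynb")
  h_write_nb(nb, path)
  original <- read_notebook(path)
  before <- snapshot_workspace(dir, exclude = "writer.ipynb")
  trace <- execute_notebook(path, h_python_handle(), timeout = 30)
  after <- snapshot_workspace(dir, exclude = "writer.ipynb")
  report <- diff_against_original(original, read_notebook(trace$executed_path),
                                  before, after)
  expect_identical(report$file_diff_count, 2L)
})

test_that("ANSI escapes and trailing whitespace are normalized before comparison", {
  stored <- h_cell("code", "p", outputs = list(h_stream("\033[31mred\033[0m text  \n")))
  fresh <- h_cell("code", "p", outputs = list(h_stream("red text\n")))
  report <- diff_against_original(h_notebook(list(stored)), h_notebook(list(fresh)))
  expect_identical(report$output_diff_count, 0L)
})

test_that("classification follows the documented precedence", {
  repo_ok <- list(available = TRUE)
  repo_gone <- list(available = FALSE)
  s_py <- structure(list(language = "python"), class = "notebook_structure")
  s_r <- structure(list(language = "r"), class = "notebook_structure")
  ok <- list(success = TRUE)
  failed <- list(success = FALSE)

  expect_identical(classify_outcome(repo_gone, s_py)$label, "repo_unavailable")
  expect_identical(classify_outcome(repo_ok, s_r)$label, "not_target_language")
  expect_identical(classify_outcome(repo_ok, NULL)$label, "no_declared_pipeline_entry")
  expect_identical(classify_outcome(repo_ok, s_py, failed)$label, "install_failed")

  timeout_trace <- list(timed_out = TRUE, kernel_start_failed = FALSE,
                        first_exception_type = NA_character_)
  expect_identical(classify_outcome(repo_ok, s_py, ok, timeout_trace)$label, "timeout")

  dead_kernel <- list(timed_out = FALSE, kernel_start_failed = TRUE,
                      first_exception_type = NA_character_)
  expect_identical(classify_outcome(repo_ok, s_py, ok, dead_kernel)$label, "excluded")

  exc <- list(timed_out = FALSE, kernel_start_failed = FALSE,
              first_exception_type = "FileNotFoundError")
  res <- classify_outcome(repo_ok, s_py, ok, exc)
  expect_identical(res$label, "exception")
  expect_identical(res$exception_type, "FileNotFoundError")
})

test_that("inconsistent pipeline prefixes violate the contract loudly", {
  repo_ok <- list(available = TRUE)
  s_py <- structure(list(language = "python"), class = "notebook_structure")
  clean <- list(timed_out = FALSE, kernel_start_failed = FALSE,
                first_exception_type = NA_character_)
  expect_error(classify_outcome(repo_ok, s_py, list(success = FALSE), clean),
               "inconsistent")
  expect_error(classify_outcome(repo_ok, s_py, list(success = TRUE), NULL),
               "inconsistent")
  expect_error(classify_outcome(repo_ok, s_py, list(success = TRUE), clean, NULL),
               "inconsistent")
})

test_that("the counter-strict policy flag flips the identity label", {
  repo_ok <- list(available = TRUE)
  s_py <- structure(list(language = "python"), class = "notebook_structure")
  ok <- list(success = TRUE)
  clean <- list(timed_out = FALSE, kernel_start_failed = FALSE,
                first_exception_type = NA_character_)
  diff <- list(output_diff_count = 0L, execcount_diff_count = 3L,
               file_diff_count = 0L)
  expect_identical(classify_outcome(repo_ok, s_py, ok, clean, diff)$label,
                   "finished_identical")
  expect_identical(classify_outcome(repo_ok, s_py, ok, clean, diff,
                                    strict_counters = TRUE)$label,
                   "finished_different")
  real_diff <- list(output_diff_count = 2L, execcount_diff_count = 0L,
                    file_diff_count = 0L)
  expect_identical(classify_outcome(repo_ok, s_py, ok, clean, real_diff)$label,
                   "finished_different")
})
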
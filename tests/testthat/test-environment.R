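# Dependency detection, environment planning, and materialization.

test_that("declaration files are detected case-insensitively at any depth", {
  repo <- tempfile(); dir.create(file.path(repo, "sub"), recursive = TRUE)
  writeLines("forgepkg", file.path(repo, "requirements.txt"))
  d1 <- detect_declarations(repo)
  expect_true(d1$has_requirements)
  expect_false(d1$has_setup)
  expect_false(d1$has_pipfile)

  writeLines("from setuptools import setup", file.path(repo, "sub", "Setup.py"))
  writeLines("[packages]", file.path(repo, "Pipfile"))
  d2 <- detect_declarations(repo)
  expect_true(d2$has_setup)
  expect_true(d2$has_pipfile)
  expect_identical(d2$declaration_paths,
                   sort(c("requirements.txt", "sub/Setup.py", "Pipfile")))

  empty <- tempfile(); dir.create(empty)
  d3 <- detect_declarations(empty)
  expect_false(any(d3$has_requirements, d3$has_setup, d3$has_pipfile))
  expect_length(d3$declaration_paths, 0)
})

fake_structure <- function(version) {
  structure(list(language = "python", language_version_full = version),
            class = "notebook_structure")
}

test_that("environment plans take the declared interpreter at minor precision", {
  decl <- structure(list(has_requirements = TRUE, has_setup = FALSE,
                         has_pipfile = FALSE,
                         declaration_paths = "requirements.txt"),
                    class = "declaration_set")
  none <- structure(list(has_requirements = FALSE, has_setup = FALSE,
                         has_pipfile = FALSE, declaration_paths = character(0)),
                    class = "declaration_set")
  spec <- plan_environment(fake_structure("3.7.4"), decl)
  expect_identical(spec$interpreter_version, "3.7")
  expect_identical(spec$dependency_source, "declared")

  fallback <- plan_environment(fake_structure(NA_character_), none,
                               default_env_policy(default_version = "3.11"))
  expect_identical(fallback$interpreter_version, "3.11")
  expect_identical(fallback$dependency_source, "distribution_bundle")

  # deterministic key; distinct scopes and versions separate
  expect_identical(plan_environment(fake_structure("3.7"), decl)$env_key,
                   plan_environment(fake_structure("3.7.9"), decl)$env_key)
  expect_false(plan_environment(fake_structure("3.7"), decl)$env_key ==
                 plan_environment(fake_structure("3.8"), decl)$env_key)
  expect_false(plan_environment(fake_structure("3.7"), decl, scope = "a")$env_key ==
                 plan_environment(fake_structure("3.7"), decl, scope = "b")$env_key)
})

test_that("materialization resolves against the local index, and failures are recorded", {
  index <- tempfile(); publish_local_index(index)
  backend <- env_backend_local_index(index)
  ws <- tempfile()

  good <- tempfile(); dir.create(good)
  writeLines("forgepkg>=0.1  # pinned loosely", file.path(good, "requirements.txt"))
  spec <- plan_environment(fake_structure("3.11"), detect_declarations(good),
                           scope = "good")
  out <- materialize_environment(spec, backend, ws, good)
  expect_true(out$success)
  expect_identical(out$failed_stage, "none")
  expect_false(out$cached)

  bad <- tempfile(); dir.create(bad)
  writeLines("no-such-package-zqx13==9.9", file.path(bad, "requirements.txt"))
  spec_bad <- plan_environment(fake_structure("3.11"), detect_declarations(bad),
                               scope = "bad")
  fail <- materialize_environment(spec_bad, backend, ws, bad)
  expect_false(fail$success)
  expect_identical(fail$failed_stage, "install")
  expect_match(fail$log_excerpt, "no-such-package-zqx13")
})

test_that("environments are cached by key: the same spec is never built twice", {
  index <- tempfile(); publish_local_index(index)
  ws <- tempfile()
  repo <- tempfile(); dir.create(repo)
  writeLines("forgepkg", file.path(repo, "requirements.txt"))
  spec <- plan_environment(fake_structure("3.11"), detect_declarations(repo),
                           scope = "cache-test")
  builds <- 0L
  counting_backend <- list(
    create = function(version) list(python = Sys.which("python")),
    install = function(handle, root, paths, bundle) {
      builds <<- builds + 1L
      list(success = TRUE, log = "ok")
    })
  first <- materialize_environment(spec, counting_backend, ws, repo)
  second <- materialize_environment(spec, counting_backend, ws, repo)
  expect_identical(builds, 1L)
  expect_true(second$cached)
  expect_true(second$success)
  expect_lt(second$duration, 1)
})

test_that("setup.py and Pipfile requirement names are parsed", {
  repo <- tempfile(); dir.create(repo)
  writeLines(c("from setuptools import setup",
               "setup(name='proj', install_requires=['forgepkg>=0.1', 'missing-dep'])"),
             file.path(repo, "setup.py"))
  writeLines(c("[packages]", 'forgepkg = "*"'), file.path(repo, "Pipfile"))
  decl <- detect_declarations(repo)
  index <- tempfile(); publish_local_index(index)
  backend <- env_backend_local_index(index)
  spec <- plan_environment(fake_structure("3.11"), decl, scope = "sp")
  out <- materialize_environment(spec, backend, tempfile(), repo)
  expect_false(out$success)
  expect_match(out$log_excerpt, "missing-dep")

  # the null backend records the plan without resolving anything
  out_null <- materialize_environment(spec, env_backend_null(), tempfile(), repo)
  expect_true(out_null$success)
})

test_that("a backend without the create/install contract is a configuration error", {
  decl <- detect_declarations(tempdir())
  spec <- plan_environment(fake_structure("3.11"), decl, scope = "cfg")
  expect_error(materialize_environment(spec, list(), tempfile(), tempdir()),
               "create")
})
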
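#!/usr/bin/env Rscript
# Step 5 — dependency declarations, imports, and environment builds.

library(nbaudit)

store <- store_load("results/store.json")
repos <- store_table(store, "repositories")
profiles <- store_table(store, "profiles")
envs <- store_table(store, "environments")

avail <- repos[repos$available, ]
decl <- data.frame(
  declaration = c("requirements.txt", "setup.py", "Pipfile", "any", "none"),
  repositories = c(sum(avail$has_requirements), sum(avail$has_setup),
                   sum(avail$has_pipfile),
                   sum(avail$has_requirements | avail$has_setup | avail$has_pipfile),
                   sum(!(avail$has_requirements | avail$has_setup | avail$has_pipfile))))
write.csv(decl, "results/declarations.csv", row.names = FALSE)
cat("Dependency declarations across available repositories:\n"); print(decl)

py <- profiles[profiles$language == "python", ]
mods <- sort(table(unlist(strsplit(py$modules_external[py$modules_external != ""], "|",
                                   fixed = TRUE))), decreasing = TRUE)
write.csv(data.frame(module = names(mods), count = as.integer(mods)),
          "results/external_modules.csv", row.names = FALSE)
cat("\nNotebooks with imports:", sum(py$n_external_modules + py$n_local_modules > 0),
    "of", nrow(py), "\n")
cat("Notebooks with local imports:", sum(py$n_local_modules > 0), "\n")
cat("Top external modules:\n"); print(head(mods, 5))

cat("\nEnvironment builds:", nrow(envs),
    "(", sum(envs$success), "resolved,", sum(!envs$success), "failed )\n")
print(envs[, c("interpreter_version", "dependency_source", "success")])
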
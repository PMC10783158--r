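#!/usr/bin/env Rscript
# Step 4 — static census: structure, languages, naming, Markdown.

library(nbaudit)

store <- store_load("results/store.json")
profiles <- store_table(store, "profiles")

langs <- summarize_corpus(store, "language")
write.csv(langs$rows, "results/languages.csv", row.names = FALSE)
cat("Notebook languages:\n"); print(langs$rows)

versions <- summarize_corpus(store, "interpreter_version")
write.csv(versions$rows, "results/interpreter_versions.csv", row.names = FALSE)
cat("\nDeclared interpreter versions:\n"); print(versions$rows)

cat("\nStructure (medians):",
    "cells", median(profiles$cells_total),
    "| code", median(profiles$code_cells),
    "| markdown", median(profiles$markdown_cells), "\n")
cat("Notebooks with Markdown cells:",
    sum(profiles$markdown_cells > 0), "of", nrow(profiles),
    "(", percentage(sum(profiles$markdown_cells > 0), nrow(profiles), 1), "%)\n")
cat("English-only Markdown:",
    percentage(sum(profiles$english_only), nrow(profiles), 1), "%\n")

naming <- data.frame(
  flag = c("untitled", "contains_copy", "contains_test",
           "not_posix_portable", "windows_disallowed"),
  count = c(sum(profiles$is_untitled), sum(profiles$contains_copy),
            sum(profiles$contains_test), sum(!profiles$posix_portable),
            sum(profiles$windows_disallowed)))
write.csv(naming, "results/naming_flags.csv", row.names = FALSE)
cat("\nNaming flags:\n"); print(naming)
cat("Mean title length:", round(mean(profiles$title_length), 1), "characters\n")
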
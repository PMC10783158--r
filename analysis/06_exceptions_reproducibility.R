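#!/usr/bin/env Rscript
# Step 6 — exception taxonomy and the finished-group comparison.

library(nbaudit)

store <- store_load("results/store.json")

exc <- summarize_corpus(store, "exception_type")
write.csv(exc$rows, "results/exceptions.csv", row.names = FALSE)
cat("Exceptions by class:\n"); print(exc$rows)

fc <- flow_counts(store)
cat("\nExceptions:", fc$exceptions, "of", fc$executed, "executed",
    "(", percentage(fc$exceptions, fc$executed, 1), "%)\n")

cmp <- compare_groups(store)
write.csv(cmp, "results/group_comparison.csv", row.names = FALSE)
cat("\nFinished notebooks, identical vs different results:\n")
print(cmp[, c("group", "notebooks", "mean_total_cells", "mean_code_cells",
              "mean_markdown_cells", "mean_md_code_ratio", "mean_differences",
              "mean_exec_time")])
cat("\nExecution time per code cell (both estimators):\n")
print(cmp[, c("group", "time_per_code_cell_ratio_of_means",
              "time_per_code_cell_mean_of_ratios")])
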
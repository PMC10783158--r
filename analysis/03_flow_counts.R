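#!/usr/bin/env Rscript
# Step 3 — stage-by-stage flow of the audit.
#
# Recomputes the conserved flow counts (articles -> linked repositories ->
# notebooks -> attempted -> install failures / executions -> exceptions /
# timeouts / finished -> identical / different) and prints them with the
# percentages the reporting layer renders.

library(nbaudit)

store <- store_load("results/store.json")
fc <- flow_counts(store)

flow <- data.frame(stage = names(unclass(fc)),
                   count = unlist(unclass(fc), use.names = FALSE))
write.csv(flow, "results/flow_counts.csv", row.names = FALSE)
print(flow)

cat("\nOf the", fc$notebooks_attempted, "attempted notebooks:\n")
cat("  install failed: ", fc$install_failed,
    " (", percentage(fc$install_failed, fc$notebooks_attempted, 2), "%)\n", sep = "")
cat("  executed:       ", fc$executed,
    " (", percentage(fc$executed, fc$notebooks_attempted, 2), "%)\n", sep = "")
cat("  raised errors:  ", fc$exceptions,
    " (", percentage(fc$exceptions, fc$executed, 1), "% of executed)\n", sep = "")
cat("  ran through:    ", fc$finished,
    " (", percentage(fc$finished, fc$notebooks_attempted, 2), "%)\n", sep = "")
ratio <- repro_ratio(fc$finished_different, fc$finished_identical)
cat("  different/(different+identical):", ratio$display, "\n")
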
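#!/usr/bin/env Rscript
# Step 7 — code-style findings across the corpus.

library(nbaudit)

store <- store_load("results/store.json")
styles <- summarize_corpus(store, "style_code")
findings <- store_table(store, "style_findings")

total <- sum(styles$rows$count)
tab <- styles$rows
tab$pct <- vapply(tab$count, function(k) percentage(k, total, 1), character(1))
write.csv(tab, "results/style_codes.csv", row.names = FALSE)

cat("Style findings:", total, "across",
    length(unique(paste(findings$repo_url, findings$relative_path))),
    "notebooks\n\n")
print(tab)
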
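# nbaudit

Automated auditing of the computational reproducibility of Jupyter
notebooks linked from full-text biomedical articles.

Publications increasingly point at repositories of notebooks as the
executable record of their analyses. Whether those notebooks still run —
and still produce the stored results — is an empirical question this
package answers at corpus scale. Given article full text in JATS XML and
the repositories it links, nbaudit:

1. extracts and normalizes every repository mention to
   `https://github.com/{owner}/{repo}` (blob/tree paths, nbviewer wrappers,
   raw hosts, `.git` suffixes; owner-only and pages links become recorded
   rejections);
2. harvests each repository's default branch and enumerates its notebooks;
3. profiles every notebook statically: cells by type, kernel language and
   version, Markdown elements and natural language, name portability,
   imports via the abstract syntax tree, PEP 8-style findings;
4. reconstructs an execution environment from the declared dependencies
   (`requirements.txt`, `setup.py`, `Pipfile`; distribution-bundle fallback
   otherwise) through an injectable backend;
5. re-executes each Python notebook **once, top to bottom**, stops at the
   first exception, and diffs fresh outputs against stored ones after
   normalization;
6. assigns one conserved outcome label per notebook — install failure,
   typed exception, timeout, finished with different results, finished
   with identical results — and reproduces the corpus-level statistics.

For `a` notebooks attempted, the flow conserves
`a = install_failed + executed`,
`executed = exceptions + timeouts + excluded + finished`, and
`finished = identical + different`; the headline reproducibility ratio is
`different / (different + identical)`.

A seeded **forge** (`forge_corpus()`) generates fully labelled offline
corpora — JATS articles with planted link dialects, repositories with every
declaration combination, a local package index, and notebooks engineered to
land in each outcome (nine exception classes, timeouts, foreign kernels,
missing metadata, unresolvable requirements) — so the entire pipeline is
testable without network access, with ground truth known per notebook.

## Worked example

```r
library(nbaudit)

workspace <- tempfile()
manifest <- forge_corpus(workspace, seed = 1)

store <- corpus_store()
run_pipeline(workspace, store,
             policy = default_env_policy(bundle = manifest$policy$bundle),
             timeout = manifest$execution_timeout)

fc <- flow_counts(store)
cat("install failed:", fc$install_failed,
    paste0("(", percentage(fc$install_failed, fc$notebooks_attempted, 2), "%)\n"))
cat("raised errors: ", fc$exceptions,
    paste0("(", percentage(fc$exceptions, fc$executed, 1), "% of executed)\n"))
cat("ran through:   ", fc$finished,
    paste0("(", percentage(fc$finished, fc$notebooks_attempted, 2), "%)\n"))
repro_ratio(fc$finished_different, fc$finished_identical)$display

recover_labels(store, manifest)$recovery
```

```
install failed: 3 (9.38%)
raised errors:  20 (69.0% of executed)
ran through:    7 (21.88%)
[1] 0.29
[1] 1
```

Of the forged corpus's 32 attempted Python notebooks, 3 fail at dependency
resolution, 20 raise a typed exception on re-execution, 2 exceed the
timeout, and 7 run through — 5 reproducing their stored outputs exactly and
2 drifting (a ratio of 0.29). The final `1` is the ground-truth recovery:
the pipeline assigned every notebook the outcome the forge engineered.

The `analysis/` directory holds the same audit as a numbered workflow
(`01_forge_corpus.R` … `07_style_report.R`); each step prints what it found
and writes its tables under `results/`.

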
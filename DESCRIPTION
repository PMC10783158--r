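Package: nbaudit
Title: Automated Reproducibility Auditing of Computational Notebooks from the Biomedical Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An audit pipeline for the computational reproducibility of Jupyter
    notebooks linked from full-text biomedical articles. Parses JATS XML for
    repository links and publication metadata, harvests the linked repositories,
    produces a static census of every notebook (structure, language, Markdown,
    naming, imports, code style), reconstructs an execution environment from
    declared dependencies, re-executes each Python notebook once from top to
    bottom, diffs the fresh outputs against the stored ones, and classifies the
    outcome (install failure, typed exception, timeout, finished with different
    or identical results). A seeded synthetic-corpus forge generates fully
    labelled offline corpora so every stage is testable without network access,
    and a reporting layer reproduces the corpus-level summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    rlang,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
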
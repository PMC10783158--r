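---
title: "Auditing the reproducibility of published computational notebooks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the reproducibility of published computational notebooks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question the pipeline answers

A growing share of biomedical articles point at repositories of Jupyter
notebooks as the executable record of their analyses. *Method
reproducibility* for such a notebook means: check out the repository, rebuild
the declared environment, run every code cell once from top to bottom, and
compare what comes out with what the authors left stored in the file. nbaudit
implements that audit as a pipeline of small, separately testable stages:

1. **Literature mining** — parse full-text article XML (JATS, as served by
   PubMed Central), collect publication metadata, and extract every
   repository mention from the abstract, body, and back matter.
2. **Link normalization** — reduce the many citation dialects (file `blob`
   paths, nbviewer wrappers, raw-content hosts, trailing `.git`, scheme-less
   forms) to the canonical `https://github.com/{owner}/{repo}`; owner-only
   links, user pages, and gists are classified rejections, not errors.
3. **Harvesting** — acquire the default branch of each linked repository
   (unavailable remotes are recorded observations), and enumerate `.ipynb`
   files, excluding editor checkpoints.
4. **Static profiling** — a census per notebook: cell counts by type, kernel
   language and interpreter version, Markdown elements and natural language,
   file-name portability, imports via the language's own abstract syntax
   tree, and code-style findings.
5. **Environment reconstruction** — detect `requirements.txt` / `setup.py` /
   `Pipfile`, plan one environment per (repository, interpreter minor
   version, declaration set), and materialize it through an injectable
   backend; a failed dependency resolution is a recorded outcome.
6. **Re-execution and diffing** — run each Python notebook once, top to
   bottom, in its notebook directory, stop at the first raised exception,
   and diff re-executed outputs against stored ones after normalization.
7. **Classification and reporting** — one mutually exclusive outcome label
   per notebook, conserved flow counts, and the corpus-level summary tables.

The outcome labels, in precedence order: `repo_unavailable`,
`not_target_language`, `no_declared_pipeline_entry` (documents that never
parsed), `install_failed`, `timeout`, `excluded` (kernel never started),
`exception` (with the exception class), `finished_different`,
`finished_identical`. Conservation is asserted after every run:
attempted = install failures + executions; executions = exceptions +
timeouts + exclusions + finished; finished = identical + different.

## Parameters that matter

- **Execution timeout** (seconds per notebook). Production default 3600 s;
  the forged desk-scale corpus pairs a 5 s timeout with timeout fixtures
  sleeping 25 s (five times the limit, robust to scheduler jitter).
- **Identity policy.** `finished_identical` requires zero output-content
  differences. Execution-count mismatches and workspace-file changes are
  recorded but excluded from the label by default; `strict_counters = TRUE`
  folds them in. Both policies are exposed because a counter-strict notion
  of identity would leave almost no notebook identical (stored counters
  reflect the authors' interactive session, not a clean top-to-bottom run).
- **Output normalization.** ANSI escape sequences are stripped and trailing
  whitespace ignored before comparison; image payloads are compared by
  digest of the decoded bytes. Masking of transient tokens (hexadecimal
  object addresses, timestamps) is off by default and available by flag —
  masking hides real nondeterminism, so it must be a conscious choice.
- **Interpreter fallback.** A notebook that declares no version runs on the
  policy default (newest configured 3.x). The declared version is honoured
  at minor precision.
- **Distribution-bundle fallback.** Repositories without declarations get
  the configured bundle (standing in for a full data-science distribution);
  it is configuration, never hardcoded, and forged corpora set it to the
  locally published package so the fallback path is exercised offline.
- **Rounding.** Printed percentages round half away from zero at the
  requested digits (9,100 of 10,388 prints as 87.6); ratios keep full
  precision internally and round to two decimals for display.

## Definitions fixed where the field is loose

- *Empty cell*: source empty or whitespace-only, regardless of cell type.
- *POSIX-portable name*: every character in `[A-Za-z0-9._-]`, not starting
  with `-`; the historic 14-character limit is a separate flag, not a
  violation. Windows-disallowed: reserved device names or `<>:"/\|?*`.
- *"Copy"/"test" in names*: case-insensitive substring matches.
- *Local import*: top-level module name resolving to a `.py` file or package
  directory anywhere under the repository root, or any relative import.
- *First exception only*: execution stops at the first raised exception;
  later errors may depend on it and are not observed. `IOError` and friends
  are recorded verbatim and also canonicalized (`OSError`) because modern
  interpreters alias them.
- *Markdown language*: the injectable detector is applied per Markdown cell
  and the profile reports the union, so a bilingual notebook is visible as
  such; the bundled detector is a small stopword classifier and any detector
  with the same `text -> code` interface can replace it. Detector-specific
  percentages on real corpora are explicitly not a target: published figures
  for minority languages are plausibly detector artifacts.
- *Style findings*: the default engine is a compact in-package checker for
  the PEP 8 codes that dominate notebook corpora (tight commas and
  operators, comment formatting, late imports, trailing semicolons), with
  strings and comments masked first. It is injectable; findings are never
  suppressed.

## What the forge emulates — and what it does not

`forge_corpus()` generates, from a seed, a fully labelled corpus: JATS
articles planting every recognized link dialect in several sections and
encodings; repository trees with each declaration-file combination
(including one whose requirement can never resolve and one repository that
does not exist at all); a local package index publishing one tiny
distribution so "declared and installable" is testable offline; and 38
notebooks covering all 15 engineered behaviors at least twice — clean
deterministic, clean but drawing unseeded entropy, nine exception classes,
timeout, non-Python kernels, missing language metadata, and install
failure. Clean-deterministic notebooks embed stored outputs produced by
actually executing the generated code once at forge time; drifting
notebooks carry a planted draw no fresh run will reproduce, keeping forged
trees byte-stable per seed. The second code cell of every notebook is
deliberately sloppy (tight `=`, tight commas, trailing semicolon) so the
corpus carries style findings without changing behavior.

The forge emulates structure, not scale or mess: real corpora have
malformed declaration files, transitive dependency conflicts, notebooks
relying on absolute paths or private data, GPU code, and interactive
widgets. Passing the round trip shows the pipeline classifies correctly
when the ground truth is known; it does not certify behavior on inputs
stranger than the forge produces. Environment materialization in the
offline backend resolves names against the local index and runs on the
system interpreter — version *selection* logic is exercised, actual
multi-version installation is not.

## Numerical and design choices

- Environment granularity is one environment per (repository, interpreter
  minor version, declaration set) — declarations live at repository level,
  and per-notebook environments would rebuild identical stacks. The
  environment key is a hash of the canonicalized spec including the
  repository scope, and outcomes are cached by key so no spec builds twice.
- Shell directives (`%magics`, `!commands`, trailing-`?` help) are stripped
  before both AST parsing and execution, and recorded separately;
  `%load_ext` names are kept because extensions such as `autoreload` bear
  on reproducibility.
- Version-3 documents are upgraded on read (worksheets flattened, heading
  cells mapped to Markdown); execution of a legacy document runs an
  upgraded copy placed beside the original so relative paths still resolve.
- Case: repository owner/name are preserved as written; deduplication for
  harvesting is case-insensitive, matching the hosting service's routing.
- Link mentions include the back matter (data availability, supplementary,
  references), and each mention records its enclosing region, so a stricter
  inclusion policy can be replayed without re-mining.
- The per-code-cell execution time in the group comparison is reported
  under both estimators — ratio of group means and mean of per-notebook
  ratios — because they differ systematically and neither is canonical.
- The store is a single-file tabular database (JSON dump of keyed tables
  with referential-integrity checks); all percentages are computed at read
  time, never stored.

## Problem sizes

The default corpus is deliberately desk-scale: 8 articles, 10 linked
repositories (one unavailable), 38 notebook files, 8 environment builds,
and a 5-second execution timeout; a full audit runs in well under a minute
on one core, and the whole test suite — which forges and audits the corpus
once and reuses it — in under half a minute. Corpus-scale behavior of the
reporting layer is exercised separately with synthetic stores at the
published corpus sizes (tens of thousands of outcome rows).

## Known limitations

Only Python notebooks are executed; R and Julia notebooks are censused and
labelled `not_target_language`. Comments inside code cells are not
analyzed. Out-of-order replay of stored execution counts is not attempted —
the audit is strictly top-to-bottom, once. The offline environment backend
does not build real isolated interpreter installations. Import statements
are profiled but never used to install dependencies; declaration files are
the only install source, which mirrors how the audited repositories
document themselves.
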
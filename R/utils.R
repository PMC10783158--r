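# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Scalar-or-NA accessor for optional fields coming out of parsed JSON/XML.
scalar_or_na <- function(x) {
  if (is.null(x) || length(x) == 0L) return(NA_character_)
  as.character(x)[[1L]]
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Paste a nbformat cell source (string or list of line strings) into one string.
collapse_source <- function(src) {
  if (is.null(src)) return("")
  if (is.list(src)) src <- unlist(src, use.names = FALSE)
  paste0(src, collapse = "")
}

# Split into lines without dropping a trailing empty line marker.
split_lines <- function(text) {
  if (identical(text, "")) return(character(0))
  strsplit(text, "\n", fixed = TRUE)[[1L]]
}

# The python interpreter used by the execution engine and the AST helper.
nbaudit_python <- function() {
  py <- Sys.getenv("NBAUDIT_PYTHON", "")
  if (nzchar(py)) return(py)
  py <- Sys.which("python3")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) stop("no python interpreter found on PATH", call. = FALSE)
  unname(py)
}

python_helper <- function(name) {
  path <- system.file("python", name, package = "nbaudit")
  if (!nzchar(path)) stop("python helper not found: ", name, call. = FALSE)
  path
}

# Deterministic sub-seed derivation, kept below 2^31.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 7919 + sum(utf8ToInt(salt)) * 131) %% 2147483587)
}

# Write a data.frame as an empty-safe CSV.
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
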
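# Internal helpers shared across modules.

# Canonical gene order used everywhere: lexicographic by id (C locale),
# so matrices and rankings are reproducible across runs and file dialects.
canonical_order <- function(ids) {
  withr_locale <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", withr_locale), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  order(ids)
}

sort_canonical <- function(ids) ids[canonical_order(ids)]

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_coex <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_coex("'%s' must be a single finite number", name)
  }
  invisible(x)
}

# Write a data.frame as TSV with an optional '# key: value' comment header.
# Floats are written with 10 significant digits.
write_tsv_file <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  if (length(comments)) writeLines(paste0("# ", comments), con)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 10, trim = TRUE, scientific = FALSE))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# TSV/CSV reader that skips '#'-comment lines and sniffs the delimiter
# unless one is given.
read_table_file <- function(path, sep = NULL, header = TRUE, row_names = NULL) {
  if (!file.exists(path)) stop_coex("file not found: %s", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 50L)
    first <- first[!startsWith(first, "#")]
    if (!length(first)) stop_coex("file is empty: %s", path)
    sep <- if (grepl("\t", first[[1]])) "\t" else ","
  }
  read.delim(path, sep = sep, header = header, comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE,
             row.names = row_names)
}

# Short stable fingerprint of a configuration list, stamped into outputs.
config_hash <- function(cfg) {
  substr(rlang::hash(cfg), 1L, 12L)
}
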
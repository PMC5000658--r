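# deterministic TSV writer: unquoted, no row names, LF line endings,
# list columns flattened to comma-joined strings
write_tsv <- function(df, path) {
  for (col in names(df)) {
    if (is.list(df[[col]]))
      df[[col]] <- vapply(df[[col]], paste, "", collapse = ",")
    if (is.logical(df[[col]]))
      df[[col]] <- as.integer(df[[col]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
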
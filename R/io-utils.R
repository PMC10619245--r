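# Shared output helpers: versioned TSV with a comment header line, and a
# TSV reader that tolerates that header.

write_tsv_versioned <- function(df, path, header) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con, useBytes = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

read_tsv_versioned <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
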
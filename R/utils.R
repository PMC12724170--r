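# internal helpers

.stop2 <- function(class, fmt, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1L))))
}

# strict TSV reader: header required, no row names
.read_tsv <- function(path, ...) {
  if (!file.exists(path))
    .stop2("fileError", "file not found: %s", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE, ...)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.require_cols <- function(df, cols, what) {
  missing_cols <- setdiff(cols, colnames(df))
  if (length(missing_cols))
    .stop2("schemaError", "%s is missing required column(s): %s",
           what, paste(missing_cols, collapse = ", "))
  invisible(TRUE)
}

# geometric mean of a strictly positive vector
.geomean <- function(x) exp(mean(log(x)))
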
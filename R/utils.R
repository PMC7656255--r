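# Shared table I/O: every table the pipeline writes is TSV with
# '#'-prefixed metadata lines (tool version, config hash, seed) ahead of the
# header row, so outputs are self-describing and byte-stable across reruns.

write_tsv_meta <- function(x, path, meta = list()) {
  stopifnot(is.data.frame(x))
  con <- file(path, open = "wt")
  on.exit(close(con))
  meta <- c(list(tool = paste0("bcpanel ", .bcpanel_version())), meta)
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, as.character(meta[[k]])), con)
  }
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv_meta <- function(path, ...) {
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE, na.strings = c("NA", ""), ...)
}

# Deterministic short hash of a configuration list (order-insensitive).
config_hash <- function(config) {
  config <- config[order(names(config))]
  txt <- paste(names(config),
               vapply(config, function(v) paste(format(v, digits = 15), collapse = ","),
                      character(1)),
               sep = "=", collapse = ";")
  tmp <- tempfile()
  writeLines(txt, tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate that a data frame carries the mandatory columns, naming the
# missing ones in the error.
require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing mandatory column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
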
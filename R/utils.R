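# small shared internals

sniffSep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (length(hdr) == 0L) stop("empty file: ", path)
  if (grepl("\t", hdr)) "\t" else ","
}

# lightweight run log: messages tagged by level, silenced via option
mzfbaLog <- function(level, ...) {
  if (isTRUE(getOption("mzFBA.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %s", level, paste0(...)))
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
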
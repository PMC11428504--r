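# Shared delimited-text I/O. All bundled and user tables are UTF-8 comma- or
# tab-separated text with a single header row; comment lines start with '#'
# and may carry key: value declarations (currently only 'units').

read_delim_auto <- function(path, comment_keys = FALSE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  keys <- list()
  for (cl in lines[is_comment]) {
    m <- regmatches(cl, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*[:=]\\s*(\\S+)", cl))[[1]]
    if (length(m) == 3) keys[[m[2]]] <- m[3]
  }
  body <- lines[!is_comment & nzchar(trimws(lines))]
  if (!length(body)) stop("empty table: ", path, call. = FALSE)
  sep <- if (grepl("\t", body[1])) "\t" else ","
  df <- utils::read.table(text = body, header = TRUE, sep = sep,
                          quote = "\"", stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "",
                          encoding = "UTF-8")
  if (comment_keys) attr(df, "header_keys") <- keys
  df
}

write_delim_utf8 <- function(df, path, header_lines = character()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(header_lines)) {
    writeLines(paste0("# ", header_lines), con, useBytes = TRUE)
  }
  txt <- utils::capture.output(
    utils::write.table(df, stdout(), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ""))
  writeLines(enc2utf8(txt), con, useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
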
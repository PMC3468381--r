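`%||%` <- function(a, b) if (is.null(a)) b else a

# branch-length arithmetic that keeps "absent" distinct from 0: a sum where
# both operands are absent stays absent, otherwise absent counts as 0
add_bl <- function(a, b) {
  if (is.null(a) && is.null(b)) return(NULL)
  (a %||% 0) + (b %||% 0)
}

bl0 <- function(x) x %||% 0

# shortest decimal representation that parses back to the same double
fmt_num <- function(x) {
  if (is.null(x)) return("")
  if (!is.finite(x)) return(as.character(x))
  for (d in 1:17) {
    s <- format(x, digits = d, scientific = NA, trim = TRUE)
    if (as.numeric(s) == x) return(s)
  }
  format(x, digits = 17, trim = TRUE)
}

read_source_text <- function(source) {
  if (inherits(source, "connection")) {
    paste(readLines(source, warn = FALSE), collapse = "\n")
  } else if (is.character(source) && length(source) == 1) {
    if (!file.exists(source)) {
      stop("cannot open source: no such file '", source, "'", call. = FALSE)
    }
    paste(readLines(source, warn = FALSE), collapse = "\n")
  } else {
    stop("source must be a file path or a connection", call. = FALSE)
  }
}

write_sink_text <- function(text, sink) {
  if (inherits(sink, "connection")) {
    writeLines(text, sink, sep = "")
  } else if (is.character(sink) && length(sink) == 1) {
    con <- file(sink, open = "w")  # truncates
    on.exit(close(con))
    writeLines(text, con, sep = "")
  } else {
    stop("sink must be a file path or a connection", call. = FALSE)
  }
  invisible(NULL)
}
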
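#' Newick dialect options
#'
#' A dialect fully determines the parse of any valid statement; there is no
#' data-dependent switching. With `internal_labels_as_confidence` (the
#' default), a bare numeric label on an internal clade is read as a support
#' value (the common convention for bootstrap output) rather than a name;
#' quoted labels are always names. Terminal labels are always names.
#' Underscores in unquoted labels are preserved verbatim for round-trip
#' fidelity; set `underscores_to_spaces` for the older convention.
#'
#' @param internal_labels_as_confidence Read bare numeric internal labels as
#'   confidences.
#' @param underscores_to_spaces Convert `_` to a space in unquoted labels.
#' @return An object of class `"newick_dialect"`.
#' @export
newick_dialect <- function(internal_labels_as_confidence = TRUE,
                           underscores_to_spaces = FALSE) {
  structure(list(
    internal_labels_as_confidence = isTRUE(internal_labels_as_confidence),
    underscores_to_spaces = isTRUE(underscores_to_spaces)
  ), class = "newick_dialect")
}

# characters that end an unquoted label / number
.nwk_delim <- c("(", ")", "[", "]", "{", "}", ",", ":", ";", "'",
                " ", "\t", "\n", "\r")

# scanner state shared by the newick and nexus readers: one tokenizer,
# two grammars
new_scanner <- function(text) {
  env <- new.env(parent = emptyenv())
  env$chars <- strsplit(text, "", fixed = TRUE)[[1]]
  env$pos <- 1L
  env$n <- length(env$chars)
  env
}

sc_peek <- function(s) if (s$pos > s$n) NA_character_ else s$chars[s$pos]

sc_advance <- function(s) {
  ch <- sc_peek(s)
  s$pos <- s$pos + 1L
  ch
}

# skip whitespace and bracketed comments (one level of nesting supported)
sc_skip <- function(s) {
  repeat {
    ch <- sc_peek(s)
    if (is.na(ch)) return(invisible(NULL))
    if (ch %in% c(" ", "\t", "\n", "\r")) {
      s$pos <- s$pos + 1L
    } else if (ch == "[") {
      start <- s$pos
      depth <- 0L
      repeat {
        ch <- sc_advance(s)
        if (is.na(ch)) {
          stop("unterminated comment starting at position ", start,
               call. = FALSE)
        }
        if (ch == "[") depth <- depth + 1L
        if (ch == "]") {
          depth <- depth - 1L
          if (depth == 0L) break
        }
      }
    } else {
      return(invisible(NULL))
    }
  }
}

# read a possibly quoted label; returns "" when no label present
sc_label <- function(s, underscores_to_spaces = FALSE) {
  sc_skip(s)
  ch <- sc_peek(s)
  if (is.na(ch)) return(list(label = "", quoted = FALSE))
  if (ch == "'") {
    start <- s$pos
    s$pos <- s$pos + 1L
    out <- character(0)
    repeat {
      ch <- sc_advance(s)
      if (is.na(ch)) {
        stop("unterminated quoted label starting at position ", start,
             call. = FALSE)
      }
      if (ch == "'") {
        if (identical(sc_peek(s), "'")) {  # doubled quote -> literal quote
          out <- c(out, "'")
          s$pos <- s$pos + 1L
        } else break
      } else out <- c(out, ch)
    }
    return(list(label = paste(out, collapse = ""), quoted = TRUE))
  }
  out <- character(0)
  repeat {
    ch <- sc_peek(s)
    if (is.na(ch) || ch %in% .nwk_delim) break
    out <- c(out, ch)
    s$pos <- s$pos + 1L
  }
  lab <- paste(out, collapse = "")
  if (underscores_to_spaces) lab <- gsub("_", " ", lab, fixed = TRUE)
  list(label = lab, quoted = FALSE)
}

sc_number <- function(s, what = "branch length") {
  sc_skip(s)
  out <- character(0)
  start <- s$pos
  repeat {
    ch <- sc_peek(s)
    if (is.na(ch) || ch %in% .nwk_delim) break
    out <- c(out, ch)
    s$pos <- s$pos + 1L
  }
  txt <- paste(out, collapse = "")
  val <- suppressWarnings(as.numeric(txt))
  if (length(out) == 0 || is.na(val)) {
    stop("invalid ", what, " '", txt, "' at position ", start, call. = FALSE)
  }
  val
}

# recursive-descent clade parser over a scanner
parse_clade_nwk <- function(s, dialect) {
  sc_skip(s)
  children <- list()
  if (identical(sc_peek(s), "(")) {
    open_pos <- s$pos
    s$pos <- s$pos + 1L
    repeat {
      children[[length(children) + 1L]] <- parse_clade_nwk(s, dialect)
      sc_skip(s)
      ch <- sc_advance(s)
      if (identical(ch, ",")) next
      if (identical(ch, ")")) break
      stop("unbalanced parentheses: group opened at position ", open_pos,
           " not closed (at position ", s$pos - 1L, ")", call. = FALSE)
    }
  }
  lab <- sc_label(s, dialect$underscores_to_spaces)
  name <- NULL
  confidence <- NULL
  if (nzchar(lab$label)) {
    num <- suppressWarnings(as.numeric(lab$label))
    if (length(children) > 0 && !lab$quoted && !is.na(num) &&
        dialect$internal_labels_as_confidence) {
      confidence <- num
    } else {
      name <- lab$label
    }
  }
  branch_length <- NULL
  sc_skip(s)
  if (identical(sc_peek(s), ":")) {
    s$pos <- s$pos + 1L
    branch_length <- sc_number(s)
  }
  clade(name = name, branch_length = branch_length,
        confidence = confidence, children = children)
}

parse_statement_nwk <- function(s, dialect) {
  root <- parse_clade_nwk(s, dialect)
  sc_skip(s)
  ch <- sc_advance(s)
  if (!identical(ch, ";")) {
    if (is.na(ch)) {
      stop("missing ';' at end of newick statement", call. = FALSE)
    }
    stop("unexpected character '", ch, "' at position ", s$pos - 1L,
         " (unbalanced parentheses or missing ';')", call. = FALSE)
  }
  phylo_tree(root, rooted = FALSE)
}

#' Parse a Newick statement
#'
#' Recursive-descent parser for the Newick standard: nested parentheses are
#' children, `label:length` after a group names the internal clade or (by
#' dialect) sets its confidence, polytomies are preserved, single-quoted
#' labels may contain structural characters (with `''` as an escaped
#' quote), and bracketed comments are skipped. Trees parsed from Newick are
#' unrooted by default, since the format carries no rootedness.
#'
#' @param text One semicolon-terminated Newick statement.
#' @param dialect A [newick_dialect()].
#' @return A [phylo_tree()].
#' @examples
#' tr <- parse_newick("((A:1,B:2)X:3,(C:4,D:5)Y:6)R:0;")
#' count_terminals(tr)
#' @export
parse_newick <- function(text, dialect = newick_dialect()) {
  s <- new_scanner(text)
  sc_skip(s)
  if (is.na(sc_peek(s))) stop("empty newick statement", call. = FALSE)
  tree <- parse_statement_nwk(s, dialect)
  sc_skip(s)
  if (!is.na(sc_peek(s))) {
    stop("trailing content after ';'; use parse_newick_many() for files ",
         "with multiple statements", call. = FALSE)
  }
  tree
}

#' Parse a file's worth of Newick statements
#'
#' @param text Text containing zero or more semicolon-terminated statements.
#' @param dialect A [newick_dialect()].
#' @return List of [phylo_tree()] objects in file order. Malformed
#'   statements are reported with their statement index.
#' @export
parse_newick_many <- function(text, dialect = newick_dialect()) {
  s <- new_scanner(text)
  out <- list()
  repeat {
    sc_skip(s)
    if (is.na(sc_peek(s))) break
    idx <- length(out) + 1L
    tree <- tryCatch(parse_statement_nwk(s, dialect), error = function(e) {
      stop("statement ", idx, ": ", conditionMessage(e), call. = FALSE)
    })
    out[[idx]] <- tree
  }
  out
}

# quote a label if it contains structural characters, whitespace or quotes
nwk_quote <- function(name) {
  if (grepl("[][(){}:;,'\"]|[[:space:]]", name)) {
    paste0("'", gsub("'", "''", name, fixed = TRUE), "'")
  } else name
}

#' Serialize a tree as a Newick statement
#'
#' Names are quoted only when they contain structural characters or
#' whitespace; numeric output uses the shortest decimal that parses back to
#' the same value; internal confidences are written in the internal-label
#' slot when the dialect reads them from there and the clade has no name.
#'
#' @param x A tree or clade.
#' @param dialect A [newick_dialect()].
#' @return A single Newick statement ending in `";"`.
#' @examples
#' serialize_newick(parse_newick("((A:1,B:2)X:3,(C:4,D:5)Y:6)R:0;"))
#' @export
serialize_newick <- function(x, dialect = newick_dialect()) {
  ser <- function(cl) {
    inner <- if (length(cl$children) > 0) {
      paste0("(", paste(vapply(cl$children, ser, character(1)),
                        collapse = ","), ")")
    } else ""
    label <- if (!is.null(cl$name)) {
      nwk_quote(cl$name)
    } else if (length(cl$children) > 0 && !is.null(cl$confidence) &&
               dialect$internal_labels_as_confidence) {
      fmt_num(cl$confidence)
    } else ""
    blen <- if (!is.null(cl$branch_length)) {
      paste0(":", fmt_num(cl$branch_length))
    } else ""
    paste0(inner, label, blen)
  }
  paste0(ser(root_of(x)), ";")
}
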
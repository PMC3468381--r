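# NEXUS support interprets only the TREES block (translate table, rooted
# markers, tree statements); other blocks are skipped verbatim. The label
# tokenizer is shared with the Newick reader: one tokenizer, two grammars.

# split text into top-level statements ending in ';', respecting quotes and
# bracketed comments (comments are kept inside the statement text so the
# [&R]/[&U] rooted markers survive)
nexus_statements <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  out <- character(0)
  buf <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "'") {
      buf <- c(buf, ch); i <- i + 1L
      while (i <= n) {
        buf <- c(buf, chars[i])
        if (chars[i] == "'") {
          if (i + 1L <= n && chars[i + 1L] == "'") {
            buf <- c(buf, chars[i + 1L]); i <- i + 2L; next
          }
          i <- i + 1L; break
        }
        i <- i + 1L
      }
    } else if (ch == "[") {
      depth <- 0L
      while (i <= n) {
        buf <- c(buf, chars[i])
        if (chars[i] == "[") depth <- depth + 1L
        if (chars[i] == "]") {
          depth <- depth - 1L
          if (depth == 0L) { i <- i + 1L; break }
        }
        i <- i + 1L
      }
    } else if (ch == ";") {
      out <- c(out, paste(buf, collapse = ""))
      buf <- character(0)
      i <- i + 1L
    } else {
      buf <- c(buf, ch)
      i <- i + 1L
    }
  }
  trimmed <- trimws(gsub("^\\s+", "", out))
  trimmed[nzchar(trimmed)]
}

# first word of a statement, lowercased, comments stripped
nexus_keyword <- function(stmt) {
  s <- gsub("\\[[^]]*\\]", " ", stmt)
  tolower(sub("^\\s*(\\S+).*$", "\\1", s))
}

parse_translate <- function(stmt) {
  body <- sub("^\\s*\\S+", "", stmt)  # drop the 'translate' keyword
  entries <- strsplit(body, ",", fixed = TRUE)[[1]]
  map <- character(0)
  for (e in entries) {
    s <- new_scanner(e)
    tok <- sc_label(s)$label
    name <- sc_label(s)$label
    if (!nzchar(tok)) next
    if (tok %in% names(map)) {
      stop("duplicate token '", tok, "' in translate table", call. = FALSE)
    }
    map[tok] <- name
  }
  map
}

apply_translate <- function(cl, map) {
  if (length(cl$children) == 0) {
    if (!is.null(cl$name) && cl$name %in% names(map)) {
      cl$name <- unname(map[cl$name])
    }
  } else {
    cl$children <- lapply(cl$children, apply_translate, map = map)
  }
  cl
}

parse_tree_statement <- function(stmt, translate, dialect) {
  # tree NAME = [&R] (...);   (the trailing ';' was consumed by the splitter)
  s <- new_scanner(stmt)
  sc_label(s)  # 'tree' keyword
  tname <- sc_label(s)$label
  sc_skip(s)
  if (!identical(sc_advance(s), "=")) {
    stop("malformed tree statement '", tname, "': expected '='",
         call. = FALSE)
  }
  rest <- substr(stmt, s$pos, nchar(stmt))
  rooted <- NA
  m <- regexpr("^\\s*\\[&([RUru])\\]", rest)
  if (m > 0) {
    flag <- toupper(gsub("[^RUru]", "", regmatches(rest, m)))
    rooted <- identical(flag, "R")
    rest <- sub("^\\s*\\[&[RUru]\\]", "", rest)
  }
  tree <- tryCatch(parse_newick(paste0(rest, ";"), dialect),
                   error = function(e) {
                     stop("malformed tree statement '", tname, "': ",
                          conditionMessage(e), call. = FALSE)
                   })
  if (!is.na(rooted)) tree$rooted <- rooted
  if (length(translate) > 0) {
    tree$root <- apply_translate(tree$root, translate)
  }
  tree$name <- if (nzchar(tname)) tname else NULL
  tree
}

#' Parse the TREES block of a NEXUS file
#'
#' Yields one tree per `tree NAME = ...;` statement in the TREES block, with
#' the TRANSLATE table (when present) applied to terminal labels, the
#' leading `[&R]`/`[&U]` comment mapped to the rootedness flag, and the tree
#' name stored on the result. Keywords are case-insensitive. A file without
#' a TREES block yields an empty list (not an error).
#'
#' @param source File path, connection, or NEXUS text.
#' @param dialect A [newick_dialect()] for the embedded tree statements.
#' @return List of [phylo_tree()] objects.
#' @examples
#' txt <- "#NEXUS\nbegin trees;\ntranslate 1 A, 2 B;\ntree t1 = [&R] (1:1,2:2);\nend;"
#' tr <- parse_nexus(txt)[[1]]
#' tr$rooted
#' @export
parse_nexus <- function(source, dialect = newick_dialect()) {
  is_literal <- is.character(source) && length(source) == 1 &&
    !file.exists(source) &&
    grepl("[\n;()]", source)  # document text, not a (mistyped) path
  text <- if (is_literal) source else read_source_text(source)
  if (!grepl("^\\s*#nexus", tolower(text))) {
    stop("not a NEXUS file: missing #NEXUS header", call. = FALSE)
  }
  text <- sub("^\\s*#\\S+", "", text)
  stmts <- nexus_statements(text)
  trees <- list()
  in_trees <- FALSE
  translate <- character(0)
  i <- 1L
  while (i <= length(stmts)) {
    kw <- nexus_keyword(stmts[i])
    if (!in_trees) {
      if (kw == "begin") {
        block <- tolower(trimws(sub("^\\s*\\S+", "",
                                    gsub("\\[[^]]*\\]", " ", stmts[i]))))
        if (block == "trees") in_trees <- TRUE
      }
    } else {
      if (kw %in% c("end", "endblock")) {
        in_trees <- FALSE
      } else if (kw == "translate") {
        translate <- parse_translate(stmts[i])
      } else if (kw == "tree") {
        trees[[length(trees) + 1L]] <-
          parse_tree_statement(stmts[i], translate, dialect)
      }
      # other statements inside the block are ignored
    }
    i <- i + 1L
  }
  trees
}

#' Serialize trees as a NEXUS TREES block
#'
#' Emits `#NEXUS` and a single TREES block with one statement per tree,
#' named `tree1..treeN` unless a tree carries a name, each with its
#' rootedness comment (`[&R]`/`[&U]`). No translate table is written —
#' terminal labels are emitted directly, which is valid per the standard
#' and round-trips cleanly.
#'
#' @param trees A tree or list of trees.
#' @param dialect A [newick_dialect()] for the embedded statements.
#' @return NEXUS document text.
#' @export
serialize_nexus <- function(trees, dialect = newick_dialect()) {
  if (inherits(trees, "phylo_tree") || inherits(trees, "clade")) {
    trees <- list(trees)
  }
  lines <- c("#NEXUS", "begin trees;")
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    nm <- if (inherits(tr, "phylo_tree")) tr$name else NULL
    nm <- nwk_quote(nm %||% paste0("tree", i))
    rooted <- if (inherits(tr, "phylo_tree") && isTRUE(tr$rooted)) "R" else "U"
    lines <- c(lines, sprintf("  tree %s = [&%s] %s", nm, rooted,
                              serialize_newick(tr, dialect)))
  }
  lines <- c(lines, "end;")
  paste0(paste(lines, collapse = "\n"), "\n")
}
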
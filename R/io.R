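# Unified I/O façade over a pluggable format registry. Format names are
# case-insensitive and always explicit — file extensions are never used for
# detection. "newick", "nexus" and "phyloxml" are always registered.

.format_registry <- new.env(parent = emptyenv())

#' Register a tree file format
#'
#' Registers (or atomically replaces) a format under a case-insensitive
#' name. The design allows simple addition of other formats without
#' touching the built-in ones.
#'
#' @param name Format name.
#' @param parser Function `(text) -> list of trees`.
#' @param writer Function `(list of trees) -> text`.
#' @return The format name, invisibly.
#' @export
register_format <- function(name, parser, writer) {
  stopifnot(is.function(parser), is.function(writer))
  assign(tolower(name), list(parser = parser, writer = writer),
         envir = .format_registry)
  invisible(name)
}

#' Names of the registered tree formats
#'
#' @return Character vector of format names.
#' @export
registered_formats <- function() {
  sort(ls(.format_registry))
}

get_format <- function(name) {
  if (!is.character(name) || length(name) != 1) {
    stop("format must be a single name", call. = FALSE)
  }
  key <- tolower(name)
  if (!exists(key, envir = .format_registry)) {
    stop("unknown format '", name, "'; registered formats are: ",
         paste(registered_formats(), collapse = ", "), call. = FALSE)
  }
  get(key, envir = .format_registry)
}

register_builtin_formats <- function() {
  register_format("newick",
                  parser = function(text) parse_newick_many(text),
                  writer = function(trees) {
                    paste0(paste(vapply(trees, serialize_newick, character(1)),
                                 collapse = "\n"),
                           if (length(trees) > 0) "\n" else "")
                  })
  register_format("nexus",
                  parser = function(text) parse_nexus(text),
                  writer = function(trees) serialize_nexus(trees))
  register_format("phyloxml",
                  parser = function(text) parse_phyloxml(text),
                  writer = function(trees) paste0(serialize_phyloxml(trees), "\n"))
}

#' Read a single tree from a file
#'
#' Accepts a file path or an already-open connection ("filename or
#' handle"); connections are consumed exactly once and never rewound. The
#' source must contain exactly one tree — use [parse_trees()] for files
#' with several.
#'
#' @param source File path or connection.
#' @param format Registered format name (case-insensitive); never guessed
#'   from the file extension.
#' @return A single [phylo_tree()].
#' @examples
#' f <- tempfile(); writeLines("((A:1,B:2)X:3,(C:4,D:5)Y:6)R:0;", f)
#' tr <- read_tree(f, "newick")
#' @export
read_tree <- function(source, format) {
  fmt <- get_format(format)
  trees <- fmt$parser(read_source_text(source))
  if (length(trees) == 0) {
    stop("no trees found in source", call. = FALSE)
  }
  if (length(trees) > 1) {
    stop("multiple trees (", length(trees),
         ") found in source; use parse_trees() to read them all",
         call. = FALSE)
  }
  trees[[1]]
}

#' Parse each of the trees a file contains
#'
#' @inheritParams read_tree
#' @return List of trees in file order (possibly empty).
#' @export
parse_trees <- function(source, format) {
  fmt <- get_format(format)
  fmt$parser(read_source_text(source))
}

#' Write a sequence of trees to a file
#'
#' An existing file is truncated. Input trees are never mutated; how the
#' rooted flag is serialized is format-specific (NEXUS `[&R]`/`[&U]`,
#' phyloXML `rooted` attribute, Newick drops it).
#'
#' @param trees A tree or list of trees.
#' @param sink File path or connection.
#' @param format Registered format name.
#' @return Number of trees written.
#' @export
write_trees <- function(trees, sink, format) {
  fmt <- get_format(format)
  if (inherits(trees, "phylo_tree") || inherits(trees, "clade")) {
    trees <- list(trees)
  }
  write_sink_text(fmt$writer(trees), sink)
  length(trees)
}

#' Convert between two tree file formats
#'
#' Equivalent to parsing then writing; returns the number of trees
#' converted. Conversion keeps the common core (topology, names, branch
#' lengths, confidences); richer annotations are narrowed per format (see
#' the package vignette).
#'
#' @param source File path or connection.
#' @param in_format,out_format Registered format names.
#' @param sink File path or connection.
#' @return Number of trees converted.
#' @export
convert_trees <- function(source, in_format, sink, out_format) {
  trees <- parse_trees(source, in_format)
  write_trees(trees, sink, out_format)
}

#' Serialize a tree as a string in the given format
#'
#' Produces exactly the bytes [write_trees()] would write for this single
#' tree.
#'
#' @param x A tree or clade.
#' @param format Registered format name.
#' @return Document text.
#' @export
format_tree <- function(x, format) {
  fmt <- get_format(format)
  fmt$writer(list(x))
}
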
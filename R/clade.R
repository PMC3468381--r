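#' Construct a clade
#'
#' A clade is one node of a phylogenetic tree together with everything below
#' it: an ordered list of child clades, nested recursively. Terminals (leaves)
#' are clades with no children. Any arity is legal; trees are not required to
#' be bifurcating. Besides the branch leading to it, a clade may carry a name,
#' a support value, and display attributes (colour and stroke width) that
#' apply to the clade and all of its descendants unless a descendant
#' overrides them.
#'
#' @param name Optional clade label.
#' @param branch_length Optional length of the branch leading to this clade
#'   (substitutions/site or arbitrary units). `NULL` means "absent", which is
#'   distinct from 0; absent lengths count as 0 only inside depth/distance
#'   sums. Negative values (which occur in neighbour-joining output) are
#'   accepted with a warning.
#' @param confidence Optional support value (e.g. bootstrap percentage).
#' @param children List of child clades, in order.
#' @param color Optional [branch_color()] applied in a cascading manner.
#' @param width Optional display stroke width, also cascading.
#' @param ... Further annotation fields (used by the phyloXML element model:
#'   `taxonomies`, `sequences`, `events`, `confidences`, `properties`,
#'   `uris`, `extras`).
#' @return An object of class `"clade"`.
#' @examples
#' tip <- clade("A", branch_length = 1)
#' cl <- clade("X", branch_length = 3, children = list(tip, clade("B", 2)))
#' is_terminal(tip)
#' @export
clade <- function(name = NULL, branch_length = NULL, confidence = NULL,
                  children = list(), color = NULL, width = NULL, ...) {
  if (!is.null(branch_length)) {
    branch_length <- as.numeric(branch_length)
    if (is.na(branch_length)) stop("branch_length must be numeric", call. = FALSE)
    if (branch_length < 0) {
      warning("negative branch length (", branch_length, ") accepted",
              call. = FALSE)
    }
  }
  if (!is.null(color) && !inherits(color, "branch_color")) {
    stop("color must be a branch_color object", call. = FALSE)
  }
  stopifnot(is.list(children))
  for (ch in children) {
    if (!inherits(ch, "clade")) stop("children must all be clades", call. = FALSE)
  }
  x <- list(
    name = if (is.null(name)) NULL else as.character(name),
    branch_length = branch_length,
    confidence = if (is.null(confidence)) NULL else as.numeric(confidence),
    color = color,
    width = if (is.null(width)) NULL else as.numeric(width),
    children = children
  )
  extra <- list(...)
  for (nm in names(extra)) x[[nm]] <- extra[[nm]]
  # the bare confidence mirrors the first Confidence annotation
  if (is.null(x$confidence) && length(x$confidences %||% list()) > 0) {
    x$confidence <- x$confidences[[1]]$value
  }
  class(x) <- "clade"
  x
}

#' Construct a whole-phylogeny tree object
#'
#' Wraps a root [clade()] with global information: whether the phylogeny is
#' rooted, and an optional identifier and name. Every inspection and
#' manipulation function in the package accepts either a tree or a bare
#' clade; on a tree it operates on the root clade.
#'
#' @param root The root clade (always present, even for a single-node tree).
#' @param rooted Logical rootedness flag.
#' @param id,name Optional identifier and name.
#' @return An object of class `"phylo_tree"`.
#' @examples
#' tr <- phylo_tree(clade("A"))
#' count_terminals(tr)
#' @export
phylo_tree <- function(root, rooted = FALSE, id = NULL, name = NULL) {
  if (!inherits(root, "clade")) stop("root must be a clade", call. = FALSE)
  structure(list(root = root, rooted = isTRUE(rooted), id = id, name = name),
            class = "phylo_tree")
}

#' Branch display colour
#'
#' An RGB colour attached to a branch. Like branch widths, colours cascade:
#' they apply to the clade and all descendants until overridden.
#'
#' @param red,green,blue Integer channels in 0..255.
#' @return An object of class `"branch_color"`.
#' @export
branch_color <- function(red, green, blue) {
  ch <- as.integer(round(c(red, green, blue)))
  if (any(is.na(ch)) || any(ch < 0L) || any(ch > 255L)) {
    stop("colour channels must be integers in [0, 255]", call. = FALSE)
  }
  structure(list(red = ch[1], green = ch[2], blue = ch[3]),
            class = "branch_color")
}

# resolve a tree-or-clade argument to its root clade
root_of <- function(x) {
  if (inherits(x, "phylo_tree")) return(x$root)
  if (inherits(x, "clade")) return(x)
  stop("expected a phylo_tree or clade, got ", paste(class(x), collapse = "/"),
       call. = FALSE)
}

# rebuild x with a new root, preserving tree wrapper fields when present
with_root <- function(x, new_root) {
  if (inherits(x, "phylo_tree")) {
    x$root <- new_root
    x
  } else {
    new_root
  }
}

# fetch the clade at an integer child-index path (empty path = root)
clade_at <- function(root, path) {
  node <- root
  for (i in path) node <- node$children[[i]]
  node
}

# apply fn to the clade at path, returning the rebuilt root
modify_at <- function(root, path, fn) {
  if (length(path) == 0) return(fn(root))
  root$children[[path[1]]] <-
    modify_at(root$children[[path[1]]], path[-1], fn)
  root
}

#' Test whether a clade is terminal
#'
#' @param x A clade or tree (a tree is terminal when its root has no
#'   children).
#' @return `TRUE` if the node has no descendants.
#' @export
is_terminal <- function(x) length(root_of(x)$children) == 0

#' @export
print.phylo_tree <- function(x, max_depth = NULL, ...) {
  cat(tree_repr(x, max_depth = max_depth), "\n", sep = "")
  invisible(x)
}

#' @export
print.clade <- function(x, max_depth = NULL, ...) {
  cat(tree_repr(x, max_depth = max_depth), "\n", sep = "")
  invisible(x)
}

#' @export
print.branch_color <- function(x, ...) {
  cat(sprintf("branch_color(%d, %d, %d)\n", x$red, x$green, x$blue))
  invisible(x)
}
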
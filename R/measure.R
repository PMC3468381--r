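# --- target resolution -----------------------------------------------------
# A "target" in any operation may be: a clade object (matched by structural
# identity, first preorder hit), a character name, a tree_query / predicate /
# attribute list, or an internal integer path.

resolve_path <- function(root, target, what = "target") {
  if (is.numeric(target) && !inherits(target, "clade")) {
    return(as.integer(target))
  }
  if (inherits(target, "clade")) {
    for (item in traverse_items(root, "preorder")) {
      if (identical(strip_attrs(item$clade), strip_attrs(target))) {
        return(item$path)
      }
    }
    stop(what, " clade not found in tree", call. = FALSE)
  }
  q <- as_query(target)
  it <- clade_iterator(root, "preorder")
  repeat {
    item <- it$nxt()
    if (is.null(item)) stop("no clade matches the given ", what, " query",
                            call. = FALSE)
    if (clade_matches(q, item$clade)) return(item$path)
  }
}

strip_attrs <- function(x) {
  attrs <- attributes(x)
  for (a in setdiff(names(attrs), c("names", "class"))) attr(x, a) <- NULL
  x
}

resolve_paths <- function(root, targets, what = "target") {
  lapply(targets, function(t) resolve_path(root, t, what))
}

# depth of the clade at `path`: sum of branch lengths from (and including)
# the root's own branch down to the clade's branch; unit mode counts edges
depth_of_path <- function(root, path, unit_branch_lengths = FALSE) {
  if (unit_branch_lengths) return(length(path))
  d <- bl0(root$branch_length)
  node <- root
  for (i in path) {
    node <- node$children[[i]]
    d <- d + bl0(node$branch_length)
  }
  d
}

common_prefix <- function(paths) {
  if (length(paths) == 1) return(paths[[1]])
  k <- min(lengths(paths))
  pre <- integer(0)
  for (j in seq_len(k)) {
    v <- paths[[1]][j]
    if (all(vapply(paths, function(p) p[j] == v, logical(1)))) {
      pre <- c(pre, v)
    } else break
  }
  pre
}

# --- measures ---------------------------------------------------------------

#' Map every clade to its depth
#'
#' Depth is the sum of branch lengths from (and including) the root's own
#' branch down to the clade's branch, so a rooted tree serialized with a
#' root branch keeps consistent depths. Absent branch lengths count as 0.
#' With `unit_branch_lengths` every edge counts 1 (the root is at 0).
#'
#' @param x A tree or clade.
#' @param unit_branch_lengths Count edges instead of summing lengths.
#' @return Named numeric vector in preorder; names are clade names where
#'   present, otherwise `"#<preorder index>"`.
#' @examples
#' tr <- parse_newick("((A:1,B:2)X:3,(C:4,D:5)Y:6)R:0;")
#' clade_depths(tr)[["D"]]
#' @export
clade_depths <- function(x, unit_branch_lengths = FALSE) {
  root <- root_of(x)
  items <- traverse_items(root, "preorder")
  out <- numeric(length(items))
  labs <- character(length(items))
  for (k in seq_along(items)) {
    out[k] <- depth_of_path(root, items[[k]]$path, unit_branch_lengths)
    labs[k] <- items[[k]]$clade$name %||% paste0("#", k)
  }
  names(out) <- labs
  out
}

#' Patristic distance between two targets
#'
#' Sum of branch lengths along the path connecting `a` and `b`, computed as
#' `depth(a) + depth(b) - 2 * depth(MRCA(a, b))`.
#'
#' @param x A tree or clade.
#' @param a,b Targets (clade, name or query).
#' @return Numeric distance.
#' @examples
#' tr <- parse_newick("((A:1,B:2)X:3,(C:4,D:5)Y:6)R:0;")
#' tree_distance(tr, "A", "D")
#' @export
tree_distance <- function(x, a, b) {
  root <- root_of(x)
  pa <- resolve_path(root, a)
  pb <- resolve_path(root, b)
  pm <- common_prefix(list(pa, pb))
  depth_of_path(root, pa) + depth_of_path(root, pb) -
    2 * depth_of_path(root, pm)
}

#' Sum of all branch lengths in the tree
#'
#' @param x A tree or clade.
#' @return Numeric; 0 for a tree without branch lengths.
#' @export
total_branch_length <- function(x) {
  tbl_clade(root_of(x))
}

tbl_clade <- function(cl) {
  bl0(cl$branch_length) +
    if (length(cl$children)) sum(vapply(cl$children, tbl_clade, numeric(1))) else 0
}

#' Most recent common ancestor of the given targets
#'
#' The deepest clade whose subtree contains all targets; a single target
#' returns itself.
#'
#' @param x A tree or clade.
#' @param ... One or more targets (clades, names or queries), or a single
#'   list of them.
#' @return The MRCA clade.
#' @examples
#' tr <- parse_newick("((A:1,B:2)X:3,(C:4,D:5)Y:6)R:0;")
#' common_ancestor(tr, "A", "B")$name
#' @export
common_ancestor <- function(x, ...) {
  targets <- list(...)
  if (length(targets) == 1 && is.list(targets[[1]]) &&
      !inherits(targets[[1]], "clade") && !inherits(targets[[1]], "tree_query")) {
    targets <- targets[[1]]
  }
  if (length(targets) == 1 && is.character(targets[[1]]) &&
      length(targets[[1]]) > 1) {
    targets <- as.list(targets[[1]])
  }
  if (length(targets) == 0) stop("no targets given", call. = FALSE)
  root <- root_of(x)
  paths <- resolve_paths(root, targets)
  clade_at(root, common_prefix(paths))
}

#' Clades directly between this root and a target
#'
#' Excludes the starting root and includes the target as last element;
#' empty when the target is the root itself.
#'
#' @param x A tree or clade.
#' @param target A clade, name or query.
#' @return List of clades along the path.
#' @export
get_path <- function(x, target) {
  root <- root_of(x)
  p <- resolve_path(root, target)
  lapply(seq_along(p), function(k) clade_at(root, p[seq_len(k)]))
}

#' Clades between two targets
#'
#' The path from `a` to `b`: the ancestors of `a` up to and including the
#' most recent common ancestor, then down to and including `b`; `a` itself
#' is excluded.
#'
#' @param x A tree or clade.
#' @param a,b Targets.
#' @return List of clades; empty when `a` and `b` coincide.
#' @examples
#' tr <- parse_newick("((A:1,B:2)X:3,(C:4,D:5)Y:6)R:0;")
#' vapply(trace_path(tr, "A", "D"), function(cl) cl$name, "")
#' @export
trace_path <- function(x, a, b) {
  root <- root_of(x)
  pa <- resolve_path(root, a)
  pb <- resolve_path(root, b)
  if (identical(pa, pb)) return(list())
  pm <- common_prefix(list(pa, pb))
  up <- list()   # ancestors of a, nearest first, down to the MRCA inclusive
  k <- length(pa) - 1L
  while (k >= length(pm)) {
    up[[length(up) + 1L]] <- clade_at(root, pa[seq_len(k)])
    k <- k - 1L
  }
  down <- lapply(seq.int(length(pm) + 1L, length.out = length(pb) - length(pm)),
                 function(j) clade_at(root, pb[seq_len(j)]))
  c(up, down)
}

#' Is the tree strictly bifurcating?
#'
#' @param x A tree or clade.
#' @return `TRUE` iff every internal clade has exactly 2 children.
#' @export
is_bifurcating <- function(x) {
  bifur <- function(cl) {
    if (length(cl$children) == 0) return(TRUE)
    length(cl$children) == 2 && all(vapply(cl$children, bifur, logical(1)))
  }
  bifur(root_of(x))
}

#' Monophyly test
#'
#' If the given terminals comprise the complete tip set of one clade,
#' return that clade (their MRCA); otherwise return `FALSE`.
#'
#' @param x A tree or clade.
#' @param terminals List (or vector of names) of terminal targets.
#' @return The MRCA clade, or `FALSE`.
#' @examples
#' tr <- parse_newick("((A:1,B:2)X:3,(C:4,D:5)Y:6)R:0;")
#' is_monophyletic(tr, c("C", "D"))$name
#' is_monophyletic(tr, c("A", "C"))
#' @export
is_monophyletic <- function(x, terminals) {
  root <- root_of(x)
  if (is.character(terminals)) terminals <- as.list(terminals)
  paths <- resolve_paths(root, terminals, what = "terminal")
  pm <- common_prefix(paths)
  mrca <- clade_at(root, pm)
  below <- lapply(Filter(function(it) is_terminal(it$clade),
                         traverse_items(mrca, "preorder")),
                  function(it) c(pm, it$path))
  key <- function(p) paste(p, collapse = ".")
  if (setequal(vapply(below, key, ""), vapply(paths, key, ""))) mrca else FALSE
}

#' Is the target contained in this tree or clade?
#'
#' Containment includes the clade itself: `is_parent_of(x, root_of(x))` is
#' `TRUE`.
#'
#' @param x A tree or clade.
#' @param target A clade, name or query.
#' @return Logical.
#' @export
is_parent_of <- function(x, target) {
  root <- root_of(x)
  !inherits(tryCatch(resolve_path(root, target), error = identity), "error")
}

#' Are all direct descendants terminal?
#'
#' A terminal clade itself is not preterminal (it has no descendants).
#'
#' @param x A tree or clade.
#' @return Logical.
#' @export
is_preterminal <- function(x) {
  cl <- root_of(x)
  length(cl$children) > 0 &&
    all(vapply(cl$children, is_terminal, logical(1)))
}
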
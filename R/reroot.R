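# Rerooting works by reversing the edges on the path from the old root down
# to the new root position. chain_child(i) rebuilds the ancestor v_i (with
# its downward child removed) as a *child* on the other side of the new
# root, recursively re-attaching v_{i-1} with the reversed edge's length.
# When the old root is left with a single child it is collapsed away
# (branch lengths summed), so path lengths between terminals are conserved.

# nodes: list of clades v_0 (old root) .. v_k along `path`
chain_nodes <- function(root, path) {
  out <- list(root)
  node <- root
  for (i in path) {
    node <- node$children[[i]]
    out[[length(out) + 1L]] <- node
  }
  out
}

# build the reversed upward chain starting at v_i (0-based level `i`),
# assigning it branch length `bl`; `path` locates v_k, nodes = chain_nodes
build_up <- function(nodes, path, i, bl) {
  node <- nodes[[i + 1L]]
  node$children[[path[i + 1L]]] <- NULL  # drop the downward child v_{i+1}
  node$branch_length <- bl
  if (i > 0L) {
    node$children <- c(node$children,
                       list(build_up(nodes, path, i - 1L,
                                     nodes[[i + 1L]]$branch_length)))
  }
  if (i == 0L && length(node$children) == 1L) {
    # former root retains one child: collapse it, summing branch lengths
    child <- node$children[[1L]]
    child$branch_length <- add_bl(child$branch_length, node$branch_length)
    return(child)
  }
  node
}

#' Reroot the tree with the specified outgroup clade
#'
#' Places the new root at the junction of the outgroup's branch and its
#' former parent: for a terminal outgroup the former parent becomes the new
#' root; an internal outgroup becomes the root itself. The outgroup keeps
#' its branch length, edges on the path from the old to the new root are
#' reversed, and a former root left with a single child is collapsed
#' (branch lengths summed). The terminal name set, the multiset of pairwise
#' terminal distances and the total branch length are invariant; the tree's
#' `rooted` flag becomes `TRUE`.
#'
#' @param x A tree (or clade).
#' @param outgroup The outgroup target (clade, name or query).
#' @param bisect Place the root at the middle of the outgroup's branch
#'   (half its length on each side) instead of at the junction.
#' @return The rerooted tree.
#' @examples
#' tr <- parse_newick("((A:1,B:2)X:3,(C:4,D:5)Y:6)R:0;")
#' serialize_newick(root_with_outgroup(tr, "C"))
#' @export
root_with_outgroup <- function(x, outgroup, bisect = FALSE) {
  root <- root_of(x)
  p <- resolve_path(root, outgroup, what = "outgroup")
  if (length(p) == 0) {
    out <- with_root(x, root)
    if (inherits(out, "phylo_tree")) out$rooted <- TRUE
    return(out)
  }
  v <- clade_at(root, p)
  old_root_bl <- root$branch_length
  if (isTRUE(bisect)) {
    half <- bl0(v$branch_length) / 2
    new_root <- reroot_on_branch(root, p, below = half, above = half)
  } else if (is_terminal(v)) {
    nodes <- chain_nodes(root, p)
    k <- length(p)
    new_root <- nodes[[k]]  # v's former parent, v stays among its children
    if (k >= 2L) {
      up <- build_up(nodes, p, k - 2L, new_root$branch_length)
      new_root$children <- c(new_root$children, list(up))
    }
    new_root$branch_length <- old_root_bl
  } else {
    nodes <- chain_nodes(root, p)
    k <- length(p)
    new_root <- v
    up <- build_up(nodes, p, k - 1L, v$branch_length)
    new_root$children <- c(new_root$children, list(up))
    new_root$branch_length <- old_root_bl
  }
  out <- with_root(x, new_root)
  if (inherits(out, "phylo_tree")) out$rooted <- TRUE
  out
}

# place a fresh root on the branch above the clade at `path`, with `below`
# of the branch on the clade's side and `above` on the former-parent side
reroot_on_branch <- function(root, path, below, above) {
  nodes <- chain_nodes(root, path)
  v <- nodes[[length(nodes)]]
  old_root_bl <- root$branch_length
  v$branch_length <- below
  up <- build_up(nodes, path, length(path) - 1L, above)
  clade(branch_length = old_root_bl, children = list(v, up))
}

#' Reroot the tree at its midpoint
#'
#' Finds the pair of terminals at maximal patristic distance and places the
#' root halfway along the path between them, so both are equidistant from
#' the new root. Ties between maximal pairs are broken by lexicographic
#' terminal-name order; a midpoint falling exactly on an existing node
#' yields a zero-length branch to that node. Total branch length is
#' conserved and the tree becomes rooted.
#'
#' @param x A tree (or clade).
#' @return The rerooted tree.
#' @examples
#' tr <- parse_newick("((A:1,B:2)X:3,(C:4,D:5)Y:6)R:0;")
#' serialize_newick(root_at_midpoint(tr))
#' @export
root_at_midpoint <- function(x) {
  root <- root_of(x)
  items <- traverse_items(root, "preorder")
  has_bl <- any(vapply(items[-1], function(it)
    !is.null(it$clade$branch_length), logical(1)))
  if (length(items) > 1 && !has_bl) {
    stop("tree has no branch lengths; assign unit branch lengths ",
         "(e.g. branch_length = 1 on every clade) before midpoint rooting",
         call. = FALSE)
  }
  tips <- Filter(function(it) is_terminal(it$clade), items)
  if (length(tips) < 2) {
    out <- with_root(x, root)
    if (inherits(out, "phylo_tree")) out$rooted <- TRUE
    return(out)
  }
  depths <- vapply(tips, function(it) depth_of_path(root, it$path), numeric(1))
  tip_names <- vapply(tips, function(it) it$clade$name %||% "", character(1))
  best <- NULL
  for (i in seq_along(tips)) {
    for (j in seq_along(tips)) {
      if (i >= j) next
      pm <- common_prefix(list(tips[[i]]$path, tips[[j]]$path))
      d <- depths[i] + depths[j] - 2 * depth_of_path(root, pm)
      nm <- sort(c(tip_names[i], tip_names[j]))
      cand <- list(d = d, i = i, j = j, key = paste(nm, collapse = "\r"))
      if (is.null(best) || d > best$d + 1e-12 ||
          (abs(d - best$d) <= 1e-12 && cand$key < best$key)) {
        best <- cand
      }
    }
  }
  # orient the walk to start from the lexicographically smaller tip
  pi_ <- tips[[best$i]]$path; pj <- tips[[best$j]]$path
  if (tip_names[best$j] < tip_names[best$i]) { tmp <- pi_; pi_ <- pj; pj <- tmp }
  pm <- common_prefix(list(pi_, pj))
  half <- best$d / 2

  # walk from tip p up to the MRCA, then down to q, edge by edge
  acc <- 0
  # upward edges: branches above v_k, v_{k-1}, ... (k = |pi_| .. |pm|+1)
  for (k in rev(seq.int(length(pm) + 1L, length.out = length(pi_) - length(pm)))) {
    node <- clade_at(root, pi_[seq_len(k)])
    blen <- bl0(node$branch_length)
    if (acc + blen >= half - 1e-12) {
      below <- half - acc          # portion adjacent to `node` (lower end)
      new_root <- reroot_on_branch(root, pi_[seq_len(k)],
                                   below = below, above = blen - below)
      return(finish_midpoint(x, new_root))
    }
    acc <- acc + blen
  }
  # downward edges toward q: branches above w at levels |pm|+1 .. |pj|
  for (k in seq.int(length(pm) + 1L, length.out = length(pj) - length(pm))) {
    node <- clade_at(root, pj[seq_len(k)])
    blen <- bl0(node$branch_length)
    if (acc + blen >= half - 1e-12) {
      t_from_top <- half - acc
      new_root <- reroot_on_branch(root, pj[seq_len(k)],
                                   below = blen - t_from_top,
                                   above = t_from_top)
      return(finish_midpoint(x, new_root))
    }
    acc <- acc + blen
  }
  stop("internal error: midpoint not located on the maximal path")
}

finish_midpoint <- function(x, new_root) {
  out <- with_root(x, new_root)
  if (inherits(out, "phylo_tree")) out$rooted <- TRUE
  out
}
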
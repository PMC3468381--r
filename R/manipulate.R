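# Manipulation functions follow R's copy-on-modify idiom: each returns the
# modified tree (or clade) rather than mutating its argument in place.

#' Sort clades by number of terminal nodes
#'
#' At every internal clade, children are sorted by their terminal count,
#' ascending by default, descending with `reverse = TRUE` (larger clades
#' first). The sort is stable, so ties keep their original order; topology,
#' names and branch lengths are unchanged as a multiset.
#'
#' @param x A tree or clade.
#' @param reverse Sort descending (most tips first).
#' @return The reordered tree/clade.
#' @examples
#' tr <- parse_newick("((A:1,B:1)X:1,C:1)R;")
#' vapply(ladderize(tr)$root$children, function(cl) cl$name, "")
#' @export
ladderize <- function(x, reverse = FALSE) {
  ladder <- function(cl) {
    if (length(cl$children) == 0) return(cl)
    cl$children <- lapply(cl$children, ladder)
    counts <- vapply(cl$children, n_terminals_clade, integer(1))
    cl$children <- cl$children[order(counts, decreasing = isTRUE(reverse),
                                     method = "radix")]
    cl
  }
  with_root(x, ladder(root_of(x)))
}

#' Prune a terminal clade from the tree
#'
#' Removes the target terminal. A non-root internal clade left with a single
#' child is collapsed by merging branch lengths (the remaining child absorbs
#' its parent's branch), so all remaining path lengths are conserved. If the
#' root itself is left with exactly one child, that child becomes the new
#' root.
#'
#' @param x A tree or clade.
#' @param target A terminal clade, name or query.
#' @return The pruned tree; the removed clade's former parent is attached as
#'   attribute `"pruned_parent"`.
#' @examples
#' tr <- parse_newick("((A:1,B:2)X:3,(C:4,D:5)Y:6)R:0;")
#' total_branch_length(prune(tr, "B"))
#' @export
prune <- function(x, target) {
  root <- root_of(x)
  p <- resolve_path(root, target)
  if (length(p) == 0) stop("cannot prune the root", call. = FALSE)
  if (!is_terminal(clade_at(root, p))) {
    stop("prune target must be a terminal clade", call. = FALSE)
  }
  parent_path <- p[-length(p)]
  idx <- p[length(p)]
  root <- modify_at(root, parent_path, function(par) {
    par$children[[idx]] <- NULL
    par
  })
  former_parent <- clade_at(root, parent_path)
  if (length(parent_path) > 0 &&
      length(clade_at(root, parent_path)$children) == 1) {
    # collapse the now single-child internal into its remaining child
    root <- modify_at(root, parent_path, function(par) {
      child <- par$children[[1]]
      child$branch_length <- add_bl(child$branch_length, par$branch_length)
      child
    })
  } else if (length(parent_path) == 0 && length(root$children) == 1) {
    child <- root$children[[1]]
    root <- child
  }
  out <- with_root(x, root)
  attr(out, "pruned_parent") <- former_parent
  out
}

#' Collapse an internal clade into its parent
#'
#' Deletes the target, relinking its children to its parent at the target's
#' position; each child's branch length grows by the target's, so all
#' pairwise terminal distances are preserved.
#'
#' @param x A tree or clade.
#' @param target An internal, non-root clade (clade, name or query).
#' @return The modified tree.
#' @examples
#' tr <- parse_newick("((A:1,B:2)X:3,(C:4,D:5)Y:6)R:0;")
#' total_branch_length(collapse_clade(tr, "X"))
#' @export
collapse_clade <- function(x, target) {
  root <- root_of(x)
  p <- resolve_path(root, target)
  if (length(p) == 0) stop("cannot collapse the root clade", call. = FALSE)
  tgt <- clade_at(root, p)
  if (is_terminal(tgt)) stop("cannot collapse a terminal clade", call. = FALSE)
  parent_path <- p[-length(p)]
  idx <- p[length(p)]
  root <- modify_at(root, parent_path, function(par) {
    kids <- lapply(tgt$children, function(ch) {
      ch$branch_length <- add_bl(ch$branch_length, tgt$branch_length)
      ch
    })
    par$children <- append(par$children[-idx], kids, after = idx - 1L)
    par
  })
  with_root(x, root)
}

#' Collapse all matching internal clades
#'
#' With no query, every non-root internal clade is collapsed, leaving a star
#' tree whose terminal branch lengths equal the original root-to-tip depths
#' (less the root's own branch). With a query, only matching non-root
#' internals are collapsed — e.g. all splits with bootstrap support below a
#' threshold.
#'
#' @param x A tree or clade.
#' @param query Optional query selecting which internals to collapse.
#' @return The modified tree.
#' @examples
#' tr <- parse_newick("((A:1,B:2)X:3,(C:4,D:5)Y:6)R:0;")
#' serialize_newick(collapse_all(tr))
#' @export
collapse_all <- function(x, query = NULL) {
  q <- if (is.null(query)) NULL else as_query(query)
  root <- root_of(x)
  repeat {
    hit <- NULL
    for (item in traverse_items(root, "preorder")) {
      if (length(item$path) == 0) next
      if (is_terminal(item$clade)) next
      if (!is.null(q) && !clade_matches(q, item$clade)) next
      hit <- item$path
      break
    }
    if (is.null(hit)) break
    root <- root_of(collapse_clade(root, hit))
  }
  with_root(x, root)
}

#' Generate new descendants of a clade
#'
#' Adds `n` new children to the target, each with the given branch length.
#' Children are named from the parent name plus a 0-based counter
#' (`"X0"`, `"X1"`, ...); an unnamed parent yields bare `"0"`, `"1"`, ....
#'
#' @param x A tree or clade.
#' @param target Clade to split; defaults to the root.
#' @param n Number of new descendants.
#' @param branch_length Branch length of each new child.
#' @return The modified tree.
#' @export
split_clade <- function(x, target = NULL, n = 2, branch_length = 1.0) {
  root <- root_of(x)
  p <- if (is.null(target)) integer(0) else resolve_path(root, target)
  root <- modify_at(root, p, function(cl) {
    prefix <- cl$name %||% ""
    new_kids <- lapply(seq_len(n) - 1L, function(i) {
      clade(name = paste0(prefix, i), branch_length = branch_length)
    })
    cl$children <- c(cl$children, new_kids)
    cl
  })
  with_root(x, root)
}

#' Create a new tree from a clade
#'
#' The clade is deep-copied (R value semantics): mutating the result leaves
#' the source unchanged.
#'
#' @param cl A clade.
#' @param rooted Rootedness flag for the new tree.
#' @return A [phylo_tree()].
#' @export
from_clade <- function(cl, rooted = FALSE) {
  phylo_tree(root_of(cl), rooted = rooted)
}

#' Create a randomized bifurcating tree
#'
#' Starts from a single root node and repeatedly splits a uniformly chosen
#' terminal until the requested taxon count is reached; names are then
#' assigned to the terminals in random order and every generated branch gets
#' the same length. The result is strictly bifurcating with `2n - 1` clades
#' for `n` taxa, and deterministic for a fixed seed.
#'
#' @param taxa Character vector of taxon names, or an integer count (names
#'   default to `t1..tn`).
#' @param branch_length Branch length assigned to every generated branch.
#' @param seed Optional integer seed; the global RNG state is restored
#'   afterwards.
#' @return A [phylo_tree()].
#' @examples
#' tr <- random_tree(8, seed = 42)
#' count_terminals(tr)
#' is_bifurcating(tr)
#' @export
random_tree <- function(taxa, branch_length = 1.0, seed = NULL) {
  if (is.numeric(taxa) && length(taxa) == 1) {
    taxa <- sprintf("t%d", seq_len(taxa))
  }
  taxa <- as.character(taxa)
  n <- length(taxa)
  if (n < 1) stop("need at least one taxon", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  root <- clade()
  term_paths <- list(integer(0))
  while (length(term_paths) < n) {
    k <- if (length(term_paths) == 1) 1L else sample.int(length(term_paths), 1)
    p <- term_paths[[k]]
    root <- modify_at(root, p, function(cl) {
      cl$children <- list(clade(branch_length = branch_length),
                          clade(branch_length = branch_length))
      cl
    })
    term_paths[[k]] <- c(p, 1L)
    term_paths[[length(term_paths) + 1L]] <- c(p, 2L)
  }
  shuffled <- if (n == 1) taxa else sample(taxa)
  k <- 0L
  name_tips <- function(cl) {
    if (length(cl$children) == 0) {
      k <<- k + 1L
      cl$name <- shuffled[k]
    } else {
      cl$children <- lapply(cl$children, name_tips)
    }
    cl
  }
  phylo_tree(name_tips(root), rooted = FALSE)
}
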
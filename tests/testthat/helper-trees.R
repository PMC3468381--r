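# Shared fixtures and oracles, all built in code.

T1_NEWICK <- "((A:1,B:2)X:3,(C:4,D:5)Y:6)R:0;"
T2_NEWICK <- "((A:1,B:1)X:1,C:1)R;"

make_t1 <- function() parse_newick(T1_NEWICK)
make_t2 <- function() parse_newick(T2_NEWICK)

clade_name <- function(cl) cl$name %||% NA_character_
`%||%` <- function(a, b) if (is.null(a)) b else a

names_of <- function(clades) vapply(clades, clade_name, character(1))
bl0 <- function(x) x %||% 0

clade_paths_snapshot <- function(tr) {
  it <- clade_iterator(tr)
  out <- list()
  repeat {
    item <- it$nxt()
    if (is.null(item)) break
    out[[length(out) + 1L]] <- item$path
  }
  out
}

# random tree with taxon-specific branch lengths on every non-root clade
rand_bl_tree <- function(n, seed) {
  tr <- random_tree(n, seed = seed)
  set.seed(seed + 1000003L)
  jitter_bl <- function(cl, is_root = FALSE) {
    if (!is_root) cl$branch_length <- round(runif(1, 0.05, 2), 4)
    cl$children <- lapply(cl$children, jitter_bl)
    cl
  }
  tr$root <- jitter_bl(tr$root, is_root = TRUE)
  tr
}

# introduce polytomies and absent names/lengths, keeping the tree valid
make_messy <- function(tr, seed) {
  set.seed(seed + 7L)
  # collapse a few random internal non-root clades -> polytomies
  repeat {
    internals <- Filter(function(p) length(p) > 0,
                        lapply(find_internal_paths(tr), identity))
    if (length(internals) == 0 || runif(1) > 0.6) break
    tr <- collapse_clade(tr, internals[[sample.int(length(internals), 1)]])
  }
  strip_some <- function(cl, is_root = FALSE) {
    if (!is_root && length(cl$children) > 0 && runif(1) < 0.5) cl$name <- NULL
    if (!is_root && runif(1) < 0.2) cl$branch_length <- NULL
    cl$children <- lapply(cl$children, strip_some)
    cl
  }
  tr$root <- strip_some(tr$root, is_root = TRUE)
  tr
}

find_internal_paths <- function(tr) {
  it <- clade_iterator(tr)
  out <- list()
  repeat {
    item <- it$nxt()
    if (is.null(item)) break
    if (length(item$path) > 0 && length(item$clade$children) > 0) {
      out[[length(out) + 1L]] <- item$path
    }
  }
  out
}

# fast boolean structural equality on the common core (no testthat overhead)
tree_identical <- function(a, b, tol = 1e-9, check_confidence = TRUE) {
  ra <- if (inherits(a, "phylo_tree")) a$root else a
  rb <- if (inherits(b, "phylo_tree")) b$root else b
  same_num <- function(x, y) {
    if (is.null(x) != is.null(y)) return(FALSE)
    is.null(x) || abs(x - y) <= tol
  }
  cmp <- function(x, y) {
    if (!identical(clade_name(x), clade_name(y))) return(FALSE)
    if (!same_num(x$branch_length, y$branch_length)) return(FALSE)
    if (check_confidence && !same_num(x$confidence, y$confidence)) return(FALSE)
    if (length(x$children) != length(y$children)) return(FALSE)
    for (i in seq_along(x$children)) {
      if (!cmp(x$children[[i]], y$children[[i]])) return(FALSE)
    }
    TRUE
  }
  cmp(ra, rb)
}

# recursive structural equality on the common core
expect_tree_equal <- function(a, b, tol = 1e-9, check_confidence = TRUE) {
  ra <- if (inherits(a, "phylo_tree")) a$root else a
  rb <- if (inherits(b, "phylo_tree")) b$root else b
  cmp <- function(x, y, where) {
    expect_identical(clade_name(x), clade_name(y),
                     label = paste0("name at ", where))
    expect_identical(is.null(x$branch_length), is.null(y$branch_length),
                     label = paste0("branch length presence at ", where))
    if (!is.null(x$branch_length)) {
      expect_equal(x$branch_length, y$branch_length, tolerance = tol,
                   label = paste0("branch length at ", where))
    }
    if (check_confidence) {
      expect_identical(is.null(x$confidence), is.null(y$confidence),
                       label = paste0("confidence presence at ", where))
      if (!is.null(x$confidence)) {
        expect_equal(x$confidence, y$confidence, tolerance = tol,
                     label = paste0("confidence at ", where))
      }
    }
    expect_identical(length(x$children), length(y$children),
                     label = paste0("arity at ", where))
    for (i in seq_along(x$children)) {
      cmp(x$children[[i]], y$children[[i]], paste0(where, "/", i))
    }
  }
  cmp(ra, rb, "root")
  invisible(TRUE)
}

# full pairwise terminal distance matrix from our own depths
tip_dist_matrix <- function(tr) {
  tips <- get_terminals(tr)
  nms <- names_of(tips)
  n <- length(nms)
  m <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        d <- tree_distance(tr, nms[i], nms[j])
        m[i, j] <- d
        m[j, i] <- d
      }
    }
  }
  m
}

# independent oracle: parse our serialization with ape
to_ape <- function(tr) {
  ape::read.tree(text = serialize_newick(tr))
}

# enumeration oracle for monophyly: the tip sets of every clade of the tree
clade_tipset_keys <- function(tr) {
  keys <- character(0)
  collect <- function(cl) {
    tips <- sort(names_of(get_terminals(cl)))
    keys <<- c(keys, paste(tips, collapse = "\r"))
    for (ch in cl$children) collect(ch)
  }
  collect(if (inherits(tr, "phylo_tree")) tr$root else tr)
  keys
}
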
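#' Lazy clade iterator
#'
#' Returns an iterator over the clades of a tree in the requested order.
#' Work is done incrementally: producing the first k items touches no more of
#' the tree than is needed, so stopping early (as [find_any()] does) skips
#' the rest of the traversal entirely. The iterator also counts how many
#' nodes it has touched, which makes the laziness observable.
#'
#' @param x A tree or clade.
#' @param order One of `"preorder"` (default), `"postorder"`,
#'   `"level-order"`.
#' @return A list with functions `nxt()` (returns `list(clade, path)` or
#'   `NULL` when exhausted) and `visited()` (number of nodes touched so far).
#' @examples
#' it <- clade_iterator(random_tree(10, seed = 1))
#' first <- it$nxt()
#' it$visited()
#' @export
clade_iterator <- function(x, order = c("preorder", "postorder", "level-order")) {
  if (!is.character(order) || !all(order %in% c("preorder", "postorder", "level-order"))) {
    stop("unknown traversal order; valid orders are: ",
         "preorder, postorder, level-order", call. = FALSE)
  }
  order <- match.arg(order)
  root <- root_of(x)
  visited <- 0L

  if (order == "preorder") {
    stack <- list(list(clade = root, path = integer(0)))
    nxt <- function() {
      if (length(stack) == 0) return(NULL)
      item <- stack[[length(stack)]]
      stack[[length(stack)]] <<- NULL
      visited <<- visited + 1L
      kids <- item$clade$children
      if (length(kids) > 0) {
        for (i in rev(seq_along(kids))) {
          stack[[length(stack) + 1L]] <<-
            list(clade = kids[[i]], path = c(item$path, i))
        }
      }
      item
    }
  } else if (order == "level-order") {
    queue <- list(list(clade = root, path = integer(0)))
    qhead <- 1L
    nxt <- function() {
      if (qhead > length(queue)) return(NULL)
      item <- queue[[qhead]]
      qhead <<- qhead + 1L
      visited <<- visited + 1L
      kids <- item$clade$children
      for (i in seq_along(kids)) {
        queue[[length(queue) + 1L]] <<-
          list(clade = kids[[i]], path = c(item$path, i))
      }
      item
    }
  } else {  # postorder: descend to deepest-left unemitted node
    # stack entries: list(clade, path, next_child_index)
    stack <- list(list(clade = root, path = integer(0), i = 1L))
    visited <- 1L
    nxt <- function() {
      while (length(stack) > 0) {
        top <- stack[[length(stack)]]
        if (top$i <= length(top$clade$children)) {
          stack[[length(stack)]]$i <<- top$i + 1L
          child <- top$clade$children[[top$i]]
          visited <<- visited + 1L
          stack[[length(stack) + 1L]] <<-
            list(clade = child, path = c(top$path, top$i), i = 1L)
        } else {
          stack[[length(stack)]] <<- NULL
          return(list(clade = top$clade, path = top$path))
        }
      }
      NULL
    }
  }
  list(nxt = nxt, visited = function() visited, order = order)
}

# eager list of all (clade, path) items in traversal order
traverse_items <- function(x, order = "preorder") {
  it <- clade_iterator(x, order)
  out <- list()
  repeat {
    item <- it$nxt()
    if (is.null(item)) break
    out[[length(out) + 1L]] <- item
  }
  out
}

# all paths in traversal order
all_paths <- function(x, order = "preorder") {
  lapply(traverse_items(x, order), `[[`, "path")
}

#' List all terminal ("leaf") clades
#'
#' @param x A tree or clade.
#' @return List of terminal clades in preorder.
#' @examples
#' tr <- parse_newick("((A:1,B:2)X:3,(C:4,D:5)Y:6)R:0;")
#' vapply(get_terminals(tr), function(cl) cl$name, "")
#' @export
get_terminals <- function(x) {
  items <- traverse_items(x, "preorder")
  lapply(Filter(function(it) is_terminal(it$clade), items), `[[`, "clade")
}

#' List all internal (non-terminal) clades
#'
#' Complement of [get_terminals()] within the set of all clades; together
#' they partition the tree.
#'
#' @inheritParams get_terminals
#' @return List of internal clades in preorder.
#' @export
get_nonterminals <- function(x) {
  items <- traverse_items(x, "preorder")
  lapply(Filter(function(it) !is_terminal(it$clade), items), `[[`, "clade")
}

#' Count the terminal nodes of a tree or clade
#'
#' @inheritParams get_terminals
#' @return Non-negative integer.
#' @export
count_terminals <- function(x) {
  n_terminals_clade(root_of(x))
}

n_terminals_clade <- function(cl) {
  if (length(cl$children) == 0) return(1L)
  sum(vapply(cl$children, n_terminals_clade, integer(1)))
}

# names of terminals, preorder
terminal_names <- function(x) {
  vapply(get_terminals(x), function(cl) cl$name %||% NA_character_,
         character(1))
}
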
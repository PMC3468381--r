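#' Declarative matcher over tree elements
#'
#' A query describes which clades or annotation elements a search should
#' match. The same query object drives every search operation
#' ([find_clades()], [find_elements()], [find_any()], and target resolution
#' in the manipulation functions). Matching is deterministic and
#' side-effect free. A plain character string used where a query is expected
#' means exact name equality; metacharacters are not interpreted unless
#' `regex = TRUE` is requested explicitly (taxon names often contain dots
#' and parentheses).
#'
#' @param name Match elements whose `name` equals this string exactly (or
#'   matches it as a regular expression when `regex = TRUE`).
#' @param ... Named attribute values; an element matches only if it carries
#'   every named field with an equal value.
#' @param predicate A function of one element returning `TRUE`/`FALSE`.
#' @param element_class Restrict matches to elements inheriting from this
#'   S3 class (e.g. `"taxonomy"`, `"clade"`).
#' @param regex Interpret `name` as a regular expression.
#' @return An object of class `"tree_query"`.
#' @examples
#' tq <- tree_query(name = "C")
#' low_support <- tree_query(predicate = function(cl)
#'   !is.null(cl$confidence) && cl$confidence < 50)
#' @export
tree_query <- function(name = NULL, ..., predicate = NULL,
                       element_class = NULL, regex = FALSE) {
  attrs <- list(...)
  if (length(attrs) > 0 && (is.null(names(attrs)) || any(names(attrs) == ""))) {
    stop("attribute query values must be named", call. = FALSE)
  }
  if (!is.null(predicate) && !is.function(predicate)) {
    stop("predicate must be a function", call. = FALSE)
  }
  structure(list(name = name, attrs = attrs, predicate = predicate,
                 element_class = element_class, regex = isTRUE(regex)),
            class = "tree_query")
}

# normalize the many accepted query spellings to a tree_query (or NULL)
as_query <- function(q) {
  if (is.null(q) || inherits(q, "tree_query")) return(q)
  if (is.character(q) && length(q) == 1) return(tree_query(name = q))
  if (is.function(q)) return(tree_query(predicate = q))
  if (is.list(q)) return(do.call(tree_query, q))
  stop("cannot interpret query of class ", paste(class(q), collapse = "/"),
       call. = FALSE)
}

# does `element` (a clade or annotation object) satisfy the query?
match_element <- function(query, element) {
  if (is.null(query)) return(TRUE)
  if (!is.null(query$element_class) &&
      !inherits(element, query$element_class)) {
    return(FALSE)
  }
  if (!is.null(query$name)) {
    nm <- element$name
    if (is.null(nm)) return(FALSE)
    ok <- if (query$regex) grepl(query$name, nm) else identical(nm, as.character(query$name))
    if (!ok) return(FALSE)
  }
  for (field in names(query$attrs)) {
    want <- query$attrs[[field]]
    have <- element[[field]]
    if (is.null(have) || length(have) != length(want)) return(FALSE)
    ok <- tryCatch(isTRUE(all(have == want)), error = function(e) FALSE)
    if (!ok) return(FALSE)
  }
  if (!is.null(query$predicate)) {
    if (!isTRUE(query$predicate(element))) return(FALSE)
  }
  TRUE
}

# the annotation sub-elements carried by a clade (phyloXML-style), flattened;
# nested protein domains are included below their sequence
sub_elements <- function(cl) {
  out <- list()
  push <- function(e) out[[length(out) + 1L]] <<- e
  for (field in c("taxonomies", "sequences", "confidences", "properties", "uris")) {
    for (e in cl[[field]] %||% list()) {
      push(e)
      if (inherits(e, "mol_sequence")) {
        for (d in e$domain_architecture$domains %||% list()) push(d)
      }
    }
  }
  if (!is.null(cl$events)) push(cl$events)
  out
}

# build the query used by find_* from either `query=` or `...`
build_query <- function(query, dots) {
  if (!is.null(query)) {
    if (length(dots) > 0) {
      stop("give either a query object or attribute arguments, not both",
           call. = FALSE)
    }
    return(as_query(query))
  }
  if (length(dots) == 0) return(NULL)
  if (length(dots) == 1 && is.null(names(dots)) ||
      (length(dots) == 1 && identical(names(dots), ""))) {
    return(as_query(dots[[1]]))
  }
  do.call(tree_query, dots)
}

#' Find clades containing a matching element
#'
#' Traverses the tree in the given order and returns each clade that itself
#' matches the query or contains a matching annotation element. With no
#' query every clade is returned, which makes this the general traversal
#' entry point.
#'
#' @param x A tree or clade.
#' @param ... Query shorthand: a single unnamed string (name equality), a
#'   predicate function, or named attribute values.
#' @param query A [tree_query()] (alternative to `...`).
#' @param order Traversal order: `"preorder"` (default), `"postorder"` or
#'   `"level-order"`.
#' @param terminal If `TRUE`/`FALSE`, keep only terminal/internal clades.
#' @return List of matching clades in traversal order.
#' @examples
#' tr <- parse_newick("((A:1,B:2)X:3,(C:4,D:5)Y:6)R:0;")
#' length(find_clades(tr, terminal = TRUE))
#' find_clades(tr, "C")[[1]]$branch_length
#' @export
find_clades <- function(x, ..., query = NULL,
                        order = c("preorder", "postorder", "level-order"),
                        terminal = NULL) {
  q <- build_query(query, list(...))
  it <- clade_iterator(x, order)
  out <- list()
  repeat {
    item <- it$nxt()
    if (is.null(item)) break
    cl <- item$clade
    if (!is.null(terminal) && is_terminal(cl) != isTRUE(terminal)) next
    if (clade_matches(q, cl)) out[[length(out) + 1L]] <- cl
  }
  out
}

clade_matches <- function(q, cl) {
  if (match_element(q, cl)) return(TRUE)
  if (is.null(q)) return(TRUE)
  for (e in sub_elements(cl)) if (match_element(q, e)) return(TRUE)
  FALSE
}

#' Find all tree elements matching the given attributes
#'
#' Like [find_clades()], but yields the matched elements themselves: for an
#' annotated clade the matching sub-element (e.g. a taxonomy) is returned
#' rather than the containing clade. On plain trees, where clades carry no
#' annotation elements, results coincide with [find_clades()].
#'
#' @inheritParams find_clades
#' @return List of matching elements in traversal order.
#' @export
find_elements <- function(x, ..., query = NULL,
                          order = c("preorder", "postorder", "level-order")) {
  q <- build_query(query, list(...))
  out <- list()
  for (item in traverse_items(x, match.arg(order))) {
    for (e in c(list(item$clade), sub_elements(item$clade))) {
      if (match_element(q, e)) out[[length(out) + 1L]] <- e
    }
  }
  out
}

#' Return the first matching element, if any
#'
#' Equivalent to the first item of [find_elements()], but the traversal
#' stops as soon as a hit is found, so no further part of the tree is
#' visited or compared.
#'
#' @inheritParams find_clades
#' @return The first matching element, or `NULL` when nothing matches
#'   (absence is a value, not an error).
#' @export
find_any <- function(x, ..., query = NULL) {
  q <- build_query(query, list(...))
  it <- clade_iterator(x, "preorder")
  repeat {
    item <- it$nxt()
    if (is.null(item)) return(NULL)
    for (e in c(list(item$clade), sub_elements(item$clade))) {
      if (match_element(q, e)) return(e)
    }
  }
}
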
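# Text rendering and 2-D layout of rooted phylograms. Layout x is the
# cumulative branch-length depth (identical to clade_depths); terminal rows
# are evenly spaced integers and each internal row is the mean of its
# children's rows.

#' Compute phylogram layout coordinates
#'
#' @param x A tree or clade.
#' @param unit_branch_lengths Count edges instead of summing branch
#'   lengths. Forced on (with a warning) when the tree carries no branch
#'   lengths at all.
#' @return Data frame with one row per clade in preorder: `label`, `x`
#'   (depth), `y` (row), `terminal`.
#' @examples
#' compute_layout(parse_newick("((A:1,B:2)X:3,(C:4,D:5)Y:6)R:0;"))
#' @export
compute_layout <- function(x, unit_branch_lengths = FALSE) {
  root <- root_of(x)
  items <- traverse_items(root, "preorder")
  if (!unit_branch_lengths && length(items) > 1 &&
      !any(vapply(items[-1], function(it)
        !is.null(it$clade$branch_length), logical(1)))) {
    warning("tree has no branch lengths; using unit branch lengths",
            call. = FALSE)
    unit_branch_lengths <- TRUE
  }
  tip_counter <- 0
  ys <- new.env(parent = emptyenv())
  ykey <- function(path) paste0("p", paste(path, collapse = "."))
  assign_y <- function(cl, path) {
    if (length(cl$children) == 0) {
      y <- tip_counter
      tip_counter <<- tip_counter + 1
    } else {
      kid_ys <- vapply(seq_along(cl$children), function(i)
        assign_y(cl$children[[i]], c(path, i)), numeric(1))
      y <- mean(kid_ys)
    }
    assign(ykey(path), y, envir = ys)
    y
  }
  assign_y(root, integer(0))
  data.frame(
    label = vapply(items, function(it) it$clade$name %||% "", character(1)),
    x = vapply(items, function(it)
      depth_of_path(root, it$path, unit_branch_lengths), numeric(1)),
    y = vapply(items, function(it)
      get(ykey(it$path), envir = ys), numeric(1)),
    terminal = vapply(items, function(it) is_terminal(it$clade), logical(1)),
    stringsAsFactors = FALSE
  )
}

#' Line segments of a phylogram
#'
#' A plotting adapter: returns the horizontal (branch) and vertical
#' (connector) segments of the rooted phylogram layout, so any graphics
#' layer can draw the tree without this package depending on one.
#'
#' @inheritParams compute_layout
#' @return Data frame with columns `x0`, `y0`, `x1`, `y1`, `type`
#'   (`"branch"`/`"connector"`), and `label` for branch segments.
#' @export
layout_segments <- function(x, unit_branch_lengths = FALSE) {
  root <- root_of(x)
  lay <- compute_layout(x, unit_branch_lengths)
  items <- traverse_items(root, "preorder")
  key <- function(p) paste0("p", paste(p, collapse = "."))
  row_of <- new.env(parent = emptyenv())
  for (k in seq_along(items)) assign(key(items[[k]]$path), k, envir = row_of)
  segs <- list()
  for (k in seq_along(items)) {
    p <- items[[k]]$path
    if (length(p) > 0) {
      parent_row <- get(key(p[-length(p)]), envir = row_of)
      segs[[length(segs) + 1L]] <- data.frame(
        x0 = lay$x[parent_row], y0 = lay$y[k],
        x1 = lay$x[k], y1 = lay$y[k],
        type = "branch", label = lay$label[k], stringsAsFactors = FALSE)
    }
    kids <- items[[k]]$clade$children
    if (length(kids) > 0) {
      kid_rows <- vapply(seq_along(kids), function(i)
        get(key(c(p, i)), envir = row_of), integer(1))
      segs[[length(segs) + 1L]] <- data.frame(
        x0 = lay$x[k], y0 = min(lay$y[kid_rows]),
        x1 = lay$x[k], y1 = max(lay$y[kid_rows]),
        type = "connector", label = "", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, segs)
}

#' Draw an ascii-art phylogram
#'
#' Monospaced rendering of a rooted phylogram: exactly one line carries
#' each terminal's name, ordered by layout row, and the horizontal extent
#' of each tip is proportional to its depth, scaled into `column_width`.
#'
#' @param x A tree or clade.
#' @param file A connection or file path passed to [cat()]; `""` prints to
#'   standard output.
#' @param column_width Total width in characters. Too-narrow widths
#'   (less than twice the longest name plus 4) trigger a warning and are
#'   widened automatically.
#' @return Invisibly, the vector of rendered lines.
#' @examples
#' draw_ascii(parse_newick("((A:1,B:2)X:3,(C:4,D:5)Y:6)R:0;"))
#' @export
draw_ascii <- function(x, file = "", column_width = 80) {
  root <- root_of(x)
  lay <- suppressWarnings(compute_layout(x))
  if (max(lay$x) == 0) lay <- compute_layout(x, unit_branch_lengths = TRUE)
  names_len <- nchar(lay$label[lay$terminal])
  longest <- if (length(names_len)) max(names_len) else 0
  if (column_width < 2 * longest + 4) {
    column_width <- 2 * longest + 4
    warning("column_width too small for the taxon names; widened to ",
            column_width, call. = FALSE)
  }
  draw_cols <- max(column_width - longest - 2, 8)
  xmax <- max(lay$x)
  scale <- if (xmax > 0) (draw_cols - 1) / xmax else 1

  items <- traverse_items(root, "preorder")
  keyf <- function(p) paste0("p", paste(p, collapse = "."))
  row_idx <- new.env(parent = emptyenv())
  for (k in seq_along(items)) assign(keyf(items[[k]]$path), k, envir = row_idx)
  # character columns, monotone along every root-to-tip path
  col <- integer(nrow(lay))
  for (k in seq_along(items)) {
    p <- items[[k]]$path
    c0 <- round(lay$x[k] * scale)
    col[k] <- if (length(p) == 0) max(c0, 0L) else {
      parent_k <- get(keyf(p[-length(p)]), envir = row_idx)
      max(col[parent_k] + 1L, c0)
    }
  }
  nrows <- as.integer(round(2 * max(lay$y))) + 1L
  canvas <- matrix(" ", nrow = max(nrows, 1), ncol = max(col) + 1L)
  rowpos <- as.integer(round(2 * lay$y)) + 1L
  for (k in seq_along(items)) {
    p <- items[[k]]$path
    if (length(p) > 0) {
      parent_k <- get(keyf(p[-length(p)]), envir = row_idx)
      c0 <- col[parent_k] + 1L
      if (c0 <= col[k]) canvas[rowpos[k], c0:col[k]] <- "_"
    }
    kids <- items[[k]]$clade$children
    if (length(kids) > 0) {
      kid_rows <- vapply(seq_along(kids), function(i)
        rowpos[get(keyf(c(p, i)), envir = row_idx)], integer(1))
      span <- seq(min(kid_rows), max(kid_rows))
      vert <- col[k] + 1L
      fill <- span[canvas[span, vert] == " "]
      canvas[fill, vert] <- "|"
    }
  }
  lines <- apply(canvas, 1, paste, collapse = "")
  for (k in seq_along(items)) {
    if (lay$terminal[k]) {
      r <- rowpos[k]
      lines[r] <- paste0(substr(lines[r], 1, col[k] + 1L), " ", lay$label[k])
    }
  }
  lines <- sub("\\s+$", "", lines)
  cat(paste0(paste(lines, collapse = "\n"), "\n"), file = file)
  invisible(lines)
}

#' Nested object-hierarchy representation of a tree
#'
#' An indented listing naming each element type and its set attributes
#' (branch length, name, confidence); unset attributes are omitted.
#' `max_depth` truncates deeper levels with an ellipsis marker.
#'
#' @param x A tree or clade.
#' @param max_depth Optional maximum clade depth to show.
#' @return A single string (lines joined with newlines).
#' @examples
#' cat(tree_repr(parse_newick("((A:1,B:2)X:3,(C:4,D:5)Y:6)R:0;")))
#' @export
tree_repr <- function(x, max_depth = NULL) {
  lines <- character(0)
  if (inherits(x, "phylo_tree")) {
    kind <- if (inherits(x, "phylogeny")) "Phylogeny" else "Tree"
    attrs <- c(
      if (!is.null(x$name)) sprintf("name='%s'", x$name),
      if (!is.null(x$id)) sprintf("id='%s'", x$id),
      sprintf("rooted=%s", if (isTRUE(x$rooted)) "TRUE" else "FALSE"))
    lines <- sprintf("%s(%s)", kind, paste(attrs, collapse = ", "))
  }
  fmt_clade <- function(cl, depth) {
    pad <- strrep("    ", depth)
    if (!is.null(max_depth) && depth > max_depth) {
      return(paste0(pad, "..."))
    }
    attrs <- c(
      if (!is.null(cl$branch_length))
        sprintf("branch_length=%s", fmt_num(cl$branch_length)),
      if (!is.null(cl$name)) sprintf("name='%s'", cl$name),
      if (!is.null(cl$confidence))
        sprintf("confidence=%s", fmt_num(cl$confidence)))
    head_line <- paste0(pad, sprintf("Clade(%s)", paste(attrs, collapse = ", ")))
    kid_lines <- character(0)
    if (length(cl$children) > 0) {
      if (!is.null(max_depth) && depth + 1 > max_depth) {
        kid_lines <- paste0(strrep("    ", depth + 1), "...")
      } else {
        kid_lines <- unlist(lapply(cl$children, fmt_clade, depth = depth + 1))
      }
    }
    c(head_line, kid_lines)
  }
  lines <- c(lines, fmt_clade(root_of(x), 0))
  paste(lines, collapse = "\n")
}
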
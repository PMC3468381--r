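test_that("layout coordinates follow depths and even tip spacing", {
  t1 <- make_t1()
  lay <- compute_layout(t1)
  row <- function(l) lay[lay$label == l, ]
  expect_equal(row("A")$y, 0)
  expect_equal(row("B")$y, 1)
  expect_equal(row("X")$y, 0.5)
  expect_equal(row("D")$x, 11)
  expect_true(all(diff(sort(lay$y[lay$terminal])) == 1))
  single <- compute_layout(parse_newick("A;"))
  expect_equal(single$x, 0)
  expect_equal(single$y, 0)
  # x is exactly the depths mapping, regardless of ladderizing
  expect_setequal(lay$x, unname(clade_depths(t1)))
  expect_setequal(compute_layout(ladderize(t1, TRUE))$x, lay$x)
})

test_that("x is monotone along every root-to-tip path", {
  for (seed in 1:10) {
    tr <- rand_bl_tree(10, seed)
    lay <- compute_layout(tr)
    for (tip in names_of(get_terminals(tr))) {
      xs <- c(clade_depths(tr)[["#1"]] %||% 0,
              vapply(get_path(tr, tip), function(cl)
                lay$x[match(cl$name %||% "", lay$label)][1], numeric(1)))
      xs <- xs[!is.na(xs)]
      expect_true(all(diff(xs) >= 0))
    }
  }
})

test_that("missing branch lengths fall back to unit layout with a warning", {
  expect_warning(lay <- compute_layout(parse_newick("((A,B),C);")),
                 "unit branch lengths")
  expect_equal(max(lay$x), 2)
})

test_that("ascii rendering puts each terminal on its own line, in order", {
  t1 <- make_t1()
  lines <- draw_ascii(t1, file = nullfile())
  named <- lines[grepl("[A-D]$", lines)]
  expect_length(named, 4)
  expect_equal(sub("^.*\\s", "", named), c("A", "B", "C", "D"))
  # deepest tip owns the right-most name column
  name_col <- vapply(named, function(l) regexpr("[A-D]$", l)[[1]], 0)
  expect_equal(names(which.max(name_col)), names(name_col)[4])  # D
  expect_match(paste(draw_ascii(parse_newick("A;"), file = nullfile()),
                     collapse = ""), "A")
})

test_that("ascii line counts with names equal the terminal count", {
  for (seed in 1:15) {
    tr <- rand_bl_tree(sample.int(20, 1) + 1, seed)
    lines <- draw_ascii(tr, file = nullfile())
    expect_length(grep("t\\d+$", lines), count_terminals(tr))
  }
})

test_that("narrow widths are widened with a warning", {
  tr <- parse_newick("(averylongtaxonname:1,B:2);")
  expect_warning(draw_ascii(tr, file = nullfile(), column_width = 10),
                 "widened")
})

test_that("the object hierarchy repr lists one line per clade", {
  t1 <- make_t1()
  txt <- tree_repr(t1)
  lines <- strsplit(txt, "\n")[[1]]
  expect_length(grep("Clade\\(", lines), 7)
  expect_match(lines[1], "rooted=FALSE")
  expect_false(any(grepl("confidence", lines)))  # unset attrs are omitted
  short <- strsplit(tree_repr(t1, max_depth = 1), "\n")[[1]]
  expect_length(grep("Clade\\(", short), 3)  # root + its two children
  expect_true(any(grepl("\\.\\.\\.", short)))
})

test_that("segments cover every branch and connector", {
  t1 <- make_t1()
  segs <- layout_segments(t1)
  expect_equal(sum(segs$type == "branch"), 6)     # every non-root clade
  expect_equal(sum(segs$type == "connector"), 3)  # every internal
  b <- segs[segs$type == "branch", ]
  expect_true(all(b$x1 >= b$x0))
})
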
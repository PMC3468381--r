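test_that("search operations find the right clades and elements", {
  t1 <- make_t1()
  expect_equal(names_of(find_clades(t1, "C")), "C")
  expect_equal(names_of(find_clades(t1, terminal = TRUE)), c("A", "B", "C", "D"))
  expect_equal(names_of(find_clades(t1, terminal = FALSE)), c("R", "X", "Y"))
  single <- parse_newick("A;")
  expect_length(find_clades(single, "Z"), 0)
  # on plain trees find_elements coincides with find_clades
  expect_equal(names_of(find_elements(t1, "X")), "X")
  expect_gte(length(find_elements(t1)), length(find_clades(t1)))
  # find_any: first preorder hit, absence is NULL
  expect_equal(find_any(t1, "D")$name, "D")
  expect_null(find_any(t1, "Z"))
  expect_equal(find_any(t1)$name, "R")
})

test_that("traversal orders are honoured and bad orders are rejected", {
  t1 <- make_t1()
  expect_equal(names_of(find_clades(t1)), c("R", "X", "A", "B", "Y", "C", "D"))
  expect_equal(names_of(find_clades(t1, order = "postorder")),
               c("A", "B", "X", "C", "D", "Y", "R"))
  expect_equal(names_of(find_clades(t1, order = "level-order")),
               c("R", "X", "Y", "A", "B", "C", "D"))
  expect_error(clade_iterator(t1, "inorder"), "preorder")
})

test_that("queries match by attribute, predicate and regex", {
  t1 <- make_t1()
  expect_equal(names_of(find_clades(t1, branch_length = 6)), "Y")
  deep <- find_clades(t1, query = function(cl)
    !is.null(cl$branch_length) && cl$branch_length > 4)
  expect_equal(names_of(deep), c("Y", "D"))
  expect_equal(names_of(find_clades(t1, query = tree_query(name = "^[AB]$",
                                                           regex = TRUE))),
               c("A", "B"))
  # plain-string queries are exact, not regex
  dot <- parse_newick("(sp.1:1,sp21:1);")
  expect_equal(length(find_clades(dot, "sp.1")), 1)
})

test_that("terminals and nonterminals partition the clades", {
  t1 <- make_t1()
  expect_equal(names_of(get_terminals(t1)), c("A", "B", "C", "D"))
  expect_equal(names_of(get_nonterminals(t1)), c("R", "X", "Y"))
  expect_equal(names_of(get_terminals(parse_newick("A;"))), "A")
  y <- find_any(t1, "Y")
  expect_equal(names_of(get_terminals(y)), c("C", "D"))
  expect_equal(count_terminals(t1), 4L)
  for (seed in 1:20) {
    tr <- random_tree(sample.int(63, 1) + 1, seed = seed)
    n_all <- length(find_clades(tr))
    expect_equal(length(get_terminals(tr)) + length(get_nonterminals(tr)),
                 n_all)
    expect_equal(count_terminals(tr), length(get_terminals(tr)))
  }
})

test_that("paths and traces follow the exclude-start include-target rule", {
  t1 <- make_t1()
  expect_equal(names_of(get_path(t1, "D")), c("Y", "D"))
  expect_length(get_path(t1, "R"), 0)
  x <- find_any(t1, "X")
  expect_equal(names_of(get_path(x, "B")), "B")
  expect_error(get_path(t1, "nope"), "no clade matches")
  expect_equal(names_of(trace_path(t1, "A", "D")), c("X", "R", "Y", "D"))
  expect_equal(names_of(trace_path(t1, "A", "B")), c("X", "B"))
  expect_length(trace_path(t1, "A", "A"), 0)
})

test_that("common ancestor is the deepest containing clade", {
  t1 <- make_t1()
  expect_equal(common_ancestor(t1, "A", "B")$name, "X")
  expect_equal(common_ancestor(t1, "A", "D")$name, "R")
  expect_equal(common_ancestor(t1, "C")$name, "C")
  expect_equal(common_ancestor(t1, c("A", "B", "C"))$name, "R")
  expect_error(common_ancestor(t1, "A", "missing"), "no clade matches")
})

test_that("depths, distances and total branch length agree with hand sums", {
  t1 <- make_t1()
  d <- clade_depths(t1)
  expect_equal(d[c("R", "X", "A", "B", "Y", "C", "D")],
               c(R = 0, X = 3, A = 4, B = 5, Y = 6, C = 10, D = 11))
  du <- clade_depths(t1, unit_branch_lengths = TRUE)
  expect_equal(du[c("R", "X", "A", "B", "Y", "C", "D")],
               c(R = 0, X = 1, A = 2, B = 2, Y = 1, C = 2, D = 2))
  expect_equal(clade_depths(parse_newick("A;")), c(A = 0))
  expect_equal(tree_distance(t1, "A", "D"), 15)
  expect_equal(tree_distance(t1, "A", "B"), 3)
  expect_equal(tree_distance(t1, "A", "A"), 0)
  expect_equal(total_branch_length(t1), 21)
  expect_equal(total_branch_length(parse_newick("(A,B);")), 0)
  expect_equal(total_branch_length(ladderize(t1)), 21)
})

test_that("distance equals the depth identity against the ape oracle", {
  for (seed in 1:15) {
    tr <- rand_bl_tree(8, seed)
    ours <- tip_dist_matrix(tr)
    ref <- cophenetic(to_ape(tr))
    expect_equal(ours[rownames(ref), colnames(ref)], ref, tolerance = 1e-9)
  }
})

test_that("topology predicates follow their definitions", {
  t1 <- make_t1()
  expect_true(is_bifurcating(t1))
  expect_false(is_bifurcating(parse_newick("(A,B,C);")))
  expect_true(is_bifurcating(parse_newick("A;")))
  expect_true(is_parent_of(t1, "D"))
  x <- find_any(t1, "X")
  expect_false(is_parent_of(x, "C"))
  expect_true(is_parent_of(t1, find_any(t1, "R")))  # self-containment
  expect_true(is_preterminal(x))
  expect_false(is_preterminal(t1))
  expect_false(is_preterminal(find_any(t1, "A")))
  expect_true(is_terminal(find_any(t1, "A")))
  expect_false(is_terminal(x))
  expect_true(is_terminal(parse_newick("A;")))
})

test_that("monophyly returns the MRCA exactly when tips form a clade", {
  t1 <- make_t1()
  expect_equal(is_monophyletic(t1, c("C", "D"))$name, "Y")
  expect_false(is_monophyletic(t1, c("A", "C")))
  expect_equal(is_monophyletic(t1, c("A", "B", "C", "D"))$name, "R")
})

test_that("ladderize sorts stably by terminal count both ways", {
  t2 <- make_t2()
  expect_equal(names_of(ladderize(t2)$root$children), c("C", "X"))
  expect_equal(names_of(ladderize(t2, reverse = TRUE)$root$children),
               c("X", "C"))
  t1 <- make_t1()
  expect_equal(serialize_newick(ladderize(t1)), T1_NEWICK)  # ties are stable
  # permutation invariant: multiset of (name, branch length) pairs unchanged
  for (seed in 1:10) {
    tr <- rand_bl_tree(12, seed)
    key <- function(t) sort(vapply(find_clades(t), function(cl)
      paste(clade_name(cl), cl$branch_length %||% NA), character(1)))
    expect_identical(key(ladderize(tr, reverse = seed %% 2 == 0)), key(tr))
  }
})

test_that("prune removes a terminal and collapses single-child internals", {
  t1 <- make_t1()
  pr <- prune(t1, "B")
  expect_equal(serialize_newick(pr), "(A:4,(C:4,D:5)Y:6)R:0;")
  expect_equal(total_branch_length(pr), 19)
  expect_equal(attr(pr, "pruned_parent")$name, "X")
  two <- prune(parse_newick("(A:1,B:1);"), "B")
  expect_equal(count_terminals(two), 1L)
  expect_equal(two$root$name, "A")
  expect_error(prune(t1, "X"), "terminal")
  for (seed in 1:10) {
    tr <- rand_bl_tree(9, seed)
    tip <- names_of(get_terminals(tr))[sample.int(9, 1)]
    expect_equal(count_terminals(prune(tr, tip)), 8L)
  }
})

test_that("collapse relinks children and preserves tip distances", {
  t1 <- make_t1()
  cl <- collapse_clade(t1, "X")
  expect_equal(serialize_newick(cl), "(A:4,B:5,(C:4,D:5)Y:6)R:0;")
  expect_equal(tree_distance(cl, "A", "C"), tree_distance(t1, "A", "C"))
  # children absorb the collapsed branch, so the total grows by
  # (arity - 1) * branch: 21 - 3 + 2 * 3
  expect_equal(total_branch_length(cl), 24)
  expect_error(collapse_clade(t1, "R"), "root")
  expect_error(collapse_clade(t1, "A"), "terminal")
})

test_that("collapse_all yields a star with root-to-tip depths, or filters", {
  t1 <- make_t1()
  star <- collapse_all(t1)
  expect_equal(serialize_newick(star), "(A:4,B:5,C:10,D:11)R:0;")
  expect_identical(serialize_newick(collapse_all(star)),
                   serialize_newick(star))
  tr <- parse_newick("((A:1,B:1)30:1,(C:1,D:1)90:1);")
  low <- collapse_all(tr, query = function(cl)
    !is.null(cl$confidence) && cl$confidence < 50)
  expect_equal(length(get_nonterminals(low)), 2)  # root + the 90 clade
  expect_equal(count_terminals(low), 4L)
})

test_that("split adds n children with generated names", {
  t1 <- make_t1()
  sp <- split_clade(t1, "D")
  expect_equal(count_terminals(sp), 5L)
  d <- find_any(sp, "D")
  expect_equal(names_of(d$children), c("D0", "D1"))
  expect_equal(vapply(d$children, function(cl) cl$branch_length, 0), c(1, 1))
  expect_equal(count_terminals(split_clade(t1, "D", n = 3)), 6L)
  anon <- split_clade(parse_newick("(A,B);"))
  expect_equal(names_of(anon$root$children)[3:4], c("0", "1"))
})

test_that("from_clade deep-copies and isolates mutation", {
  t1 <- make_t1()
  sub <- from_clade(find_any(t1, "X"))
  expect_equal(sort(names_of(get_terminals(sub))), c("A", "B"))
  sub$root$children[[1]]$name <- "ZZZ"
  expect_equal(names_of(get_terminals(t1)), c("A", "B", "C", "D"))
  whole <- from_clade(t1$root)
  expect_tree_equal(whole, t1)
})

test_that("random trees are bifurcating, complete and seed-deterministic", {
  tr <- random_tree(3, seed = 5)
  expect_equal(count_terminals(tr), 3L)
  expect_length(find_clades(tr), 5)
  expect_true(is_bifurcating(tr))
  expect_equal(count_terminals(random_tree(1, seed = 1)), 1L)
  expect_identical(serialize_newick(random_tree(20, seed = 9)),
                   serialize_newick(random_tree(20, seed = 9)))
  named <- random_tree(c("a", "b", "c"), seed = 2)
  expect_setequal(names_of(get_terminals(named)), c("a", "b", "c"))
  expect_equal(find_clades(named)[[2]]$branch_length, 1)
})

test_that("consuming one item from the iterator touches almost nothing", {
  big <- random_tree(10000, seed = 11)
  it <- clade_iterator(big)
  first <- it$nxt()
  expect_length(first$path, 0)
  height <- max(clade_depths(big, unit_branch_lengths = TRUE))
  expect_lte(it$visited(), height + 1)
})
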
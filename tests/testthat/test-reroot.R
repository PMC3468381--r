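test_that("outgroup rerooting matches the worked example and is idempotent", {
  t1 <- make_t1()
  rr <- root_with_outgroup(t1, "C")
  expect_true(rr$rooted)
  expect_equal(serialize_newick(rr), "(C:4,D:5,(A:1,B:2)X:9)Y:0;")
  expect_equal(tree_distance(rr, "A", "C"), 14)
  again <- root_with_outgroup(rr, "C")
  expect_equal(serialize_newick(again), serialize_newick(rr))
})

test_that("outgroup rerooting can bisect the outgroup branch on request", {
  t1 <- make_t1()
  rr <- root_with_outgroup(t1, "C", bisect = TRUE)
  expect_equal(tree_distance(rr, "C", "D"), 9)  # distances still conserved
  expect_equal(clade_depths(rr)[["C"]], 2)      # half of C's branch each side
  expect_equal(total_branch_length(rr), 21)
})

test_that("rerooting on an internal outgroup reverses the upward chain", {
  t1 <- make_t1()
  rr <- root_with_outgroup(t1, "X")
  expect_setequal(names_of(get_terminals(rr)), c("A", "B", "C", "D"))
  expect_equal(total_branch_length(rr), 21)
  expect_equal(tree_distance(rr, "A", "D"), 15)
  expect_equal(rr$root$name, "X")
})

test_that("an unknown outgroup is an error", {
  expect_error(root_with_outgroup(make_t1(), "nope"), "no clade matches")
})

test_that("midpoint rooting balances the two most distant terminals", {
  t1 <- make_t1()
  mp <- root_at_midpoint(t1)
  expect_true(mp$rooted)
  # max pair is (B, D) at distance 16; the root splits branch Y-R into 3+3
  kids <- mp$root$children
  expect_setequal(names_of(kids), c("X", "Y"))
  bl <- vapply(kids, function(cl) cl$branch_length, 0)
  expect_equal(sort(bl), c(3, 6))
  d <- clade_depths(mp)
  expect_equal(d[["B"]], 8)
  expect_equal(d[["D"]], 8)
  expect_equal(total_branch_length(mp), 21)
})

test_that("midpoint rooting requires branch lengths", {
  expect_error(root_at_midpoint(parse_newick("((A,B),C);")),
               "unit branch length")
})

test_that("a midpoint falling on a node yields a zero-length branch", {
  # the A-D path has length 14 and its midpoint sits exactly on node cd
  tr <- parse_newick("(A:2,(B:1,(C:1,D:7)cd:3)bc:2);")
  mp <- root_at_midpoint(tr)
  kids <- mp$root$children
  cd <- kids[[which(names_of(kids) == "cd")]]
  expect_equal(cd$branch_length, 0)
  d <- clade_depths(mp)
  expect_equal(d[["A"]], 7)
  expect_equal(d[["D"]], 7)
  expect_equal(total_branch_length(mp), total_branch_length(tr))
})

test_that("both reroot forms preserve tips, distances and total length", {
  for (seed in 1:15) {
    tr <- rand_bl_tree(sample.int(13, 1) + 3, seed)
    tips <- sort(names_of(get_terminals(tr)))
    ref <- tip_dist_matrix(tr)[tips, tips]
    out_tip <- tips[sample.int(length(tips), 1)]
    for (rr in list(root_with_outgroup(tr, out_tip), root_at_midpoint(tr))) {
      expect_identical(sort(names_of(get_terminals(rr))), tips)
      expect_equal(tip_dist_matrix(rr)[tips, tips], ref, tolerance = 1e-9)
      expect_equal(total_branch_length(rr), total_branch_length(tr),
                   tolerance = 1e-9)
    }
  }
})

test_that("rerooting at every node yields one placement per clade", {
  for (seed in 1:5) {
    tr <- rand_bl_tree(sample.int(8, 1) + 2, seed)
    n_terminal <- count_terminals(tr)
    n_internal_nonroot <- length(find_internal_paths(tr))
    paths <- lapply(clade_paths_snapshot(tr), identity)
    trees <- lapply(paths, function(p) {
      if (length(p) == 0) tr else root_with_outgroup(tr, p)
    })
    expect_length(trees, n_terminal + n_internal_nonroot + 1)
    f <- tempfile()
    expect_equal(write_trees(trees, f, "newick"), length(trees))
    expect_length(parse_trees(f, "newick"), length(trees))
  }
})
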
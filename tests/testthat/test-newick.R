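test_that("the parser handles polytomies, dialect confidences and quoting", {
  tr <- parse_newick("(A:0.1,B:0.2,(C:0.3,D:0.4):0.5);")
  expect_equal(count_terminals(tr), 4L)
  expect_length(tr$root$children, 3)
  expect_equal(tr$root$children[[3]]$branch_length, 0.5)
  expect_false(tr$rooted)

  tr <- parse_newick("((A,B)95:0.5,C);")
  inner <- tr$root$children[[1]]
  expect_equal(inner$confidence, 95)
  expect_null(inner$name)
  # same text with the dialect turned off keeps the label as a name
  tr2 <- parse_newick("((A,B)95:0.5,C);",
                      newick_dialect(internal_labels_as_confidence = FALSE))
  expect_equal(tr2$root$children[[1]]$name, "95")
  # quoted labels are always names, even numeric ones
  tr3 <- parse_newick("((A,B)'95':0.5,C);")
  expect_equal(tr3$root$children[[1]]$name, "95")

  tq <- parse_newick("('Homo sapiens':1,'It''s':2);")
  expect_equal(names_of(get_terminals(tq)), c("Homo sapiens", "It's"))
})

test_that("underscores are kept verbatim unless the dialect converts them", {
  tr <- parse_newick("(Homo_sapiens:1,Pan:2);")
  expect_equal(tr$root$children[[1]]$name, "Homo_sapiens")
  tr2 <- parse_newick("(Homo_sapiens:1,Pan:2);",
                      newick_dialect(underscores_to_spaces = TRUE))
  expect_equal(tr2$root$children[[1]]$name, "Homo sapiens")
})

test_that("comments are skipped and whitespace is insignificant", {
  tr <- parse_newick("( A : 1 , [a comment [nested]] B : 2 ) ;")
  expect_equal(names_of(get_terminals(tr)), c("A", "B"))
  expect_equal(tr$root$children[[2]]$branch_length, 2)
})

test_that("the serializer quotes minimally and round-trips exactly", {
  t1 <- make_t1()
  expect_identical(serialize_newick(t1), T1_NEWICK)
  sp <- phylo_tree(clade(children = list(clade("my taxon", 1))))
  expect_match(serialize_newick(sp), "'my taxon'", fixed = TRUE)
  expect_identical(serialize_newick(parse_newick("(,);")), "(,);")
  conf <- parse_newick("((A,B)95:0.5,C);")
  expect_identical(serialize_newick(conf), "((A,B)95:0.5,C);")
})

test_that("parse then serialize is the identity on random messy trees", {
  for (seed in 1:40) {
    tr <- make_messy(rand_bl_tree(sample.int(63, 1) + 1, seed), seed)
    text <- serialize_newick(tr)
    expect_tree_equal(parse_newick(text), tr)
  }
})

test_that("errors are positioned and truncation never yields a silent tree", {
  expect_error(parse_newick("((A,B);"), "unbalanced|position")
  expect_error(parse_newick("(A,B)"), "';'")
  expect_error(parse_newick("('Abc:1,B:2);"), "unterminated quote")
  expect_error(parse_newick("(A:x,B:2);"), "branch length")
  expect_error(parse_newick(""), "empty")
  full <- "((A:1,'B B':2)90:3,(C:4,D:5)Y:6)R:0;"
  for (cut in seq_len(nchar(full) - 1)) {
    expect_error(parse_newick(substr(full, 1, cut)),
                 label = sprintf("truncation at %d", cut))
  }
})

test_that("multiple statements split correctly and report their index", {
  trees <- parse_newick_many("(A);(B,C);")
  expect_length(trees, 2)
  expect_length(parse_newick_many(""), 0)
  expect_error(parse_newick_many("(A);(B,C"), "statement 2")
  # semicolons inside quotes do not split statements
  trees <- parse_newick_many("('a;b':1,C:2);(D,E);")
  expect_length(trees, 2)
  expect_equal(trees[[1]]$root$children[[1]]$name, "a;b")
})

test_that("negative branch lengths parse with a warning", {
  expect_warning(tr <- parse_newick("(A:-0.01,B:2);"), "negative")
  expect_equal(tr$root$children[[1]]$branch_length, -0.01)
})

test_that("our serialization is read identically by ape", {
  for (seed in 1:10) {
    tr <- rand_bl_tree(10, seed)
    ap <- to_ape(tr)
    expect_setequal(ap$tip.label, names_of(get_terminals(tr)))
    expect_equal(sum(ap$edge.length), total_branch_length(tr), tolerance = 1e-9)
  }
})
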
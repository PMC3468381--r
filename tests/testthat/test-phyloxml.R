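test_that("minimal and multi-phylogeny documents parse", {
  doc <- paste0("<phyloxml xmlns=\"http://www.phyloxml.org\">",
                "<phylogeny rooted=\"true\"><clade><name>A</name></clade>",
                "</phylogeny></phyloxml>")
  ph <- parse_phyloxml(doc)
  expect_length(ph, 1)
  expect_equal(count_terminals(ph[[1]]), 1L)
  expect_equal(ph[[1]]$root$name, "A")

  three <- paste0("<phyloxml xmlns=\"http://www.phyloxml.org\">",
                  paste0("<phylogeny rooted=\"false\"><clade><name>p",
                         1:3, "</name></clade></phylogeny>", collapse = ""),
                  "</phyloxml>")
  phs <- parse_phyloxml(three)
  expect_equal(vapply(phs, function(p) p$root$name, ""),
               c("p1", "p2", "p3"))
})

test_that("a missing rooted attribute is an error naming the phylogeny", {
  doc <- paste0("<phyloxml xmlns=\"http://www.phyloxml.org\">",
                "<phylogeny><name>oops</name><clade/></phylogeny></phyloxml>")
  expect_error(parse_phyloxml(doc), "oops")
})

test_that("branch length is accepted as attribute or child element", {
  attr_doc <- paste0("<phyloxml><phylogeny rooted=\"true\">",
                     "<clade><clade branch_length=\"0.5\"><name>A</name></clade>",
                     "</clade></phylogeny></phyloxml>")
  child_doc <- paste0("<phyloxml><phylogeny rooted=\"true\">",
                      "<clade><clade><name>A</name>",
                      "<branch_length>0.5</branch_length></clade>",
                      "</clade></phylogeny></phyloxml>")
  a <- parse_phyloxml(attr_doc)[[1]]
  b <- parse_phyloxml(child_doc)[[1]]
  expect_equal(a$root$children[[1]]$branch_length, 0.5)
  expect_equal(b$root$children[[1]]$branch_length, 0.5)
})

test_that("every element type round-trips field for field", {
  ph <- full_fixture()
  xml <- serialize_phyloxml(list(ph))
  expect_no_error(xml2::read_xml(xml))  # well-formed, namespaced
  back <- parse_phyloxml(xml)[[1]]
  expect_phylogeny_equal(back, ph)
  # foreign elements are preserved verbatim (modulo namespace prefixes)
  expect_match(xml, "kept")
  expect_length(back$root$children[[1]]$children[[2]]$extras, 1)
  expect_match(back$extras, "2005")
  # and a second cycle is stable
  again <- parse_phyloxml(serialize_phyloxml(list(back)))[[1]]
  expect_phylogeny_equal(again, back)
})

test_that("plain trees promote losslessly and idempotently", {
  t1 <- make_t1()
  ph <- as_phyloxml(t1)
  expect_s3_class(ph, "phylogeny")
  back <- parse_phyloxml(serialize_phyloxml(list(ph)))[[1]]
  expect_tree_equal(back, t1, check_confidence = FALSE)
  expect_identical(as_phyloxml(ph), ph)
  conf <- as_phyloxml(parse_newick("((A,B)95:0.5,C);"))
  inner <- conf$root$children[[1]]
  expect_equal(inner$confidences[[1]]$value, 95)
  expect_equal(inner$confidences[[1]]$type, "unknown")
})

test_that("colors and widths cascade attributes survive a round-trip", {
  root <- clade(name = "r", color = branch_color(0, 0, 255), width = 3,
                children = list(clade("A", 1), clade("B", 1)))
  back <- parse_phyloxml(serialize_phyloxml(
    list(phylogeny(root, rooted = TRUE))))[[1]]
  expect_equal(back$root$color, branch_color(0, 0, 255))
  expect_equal(back$root$width, 3)
  # cascade stays virtual: children carry no explicit color of their own
  expect_null(back$root$children[[1]]$color)
})

test_that("to_alignment collects aligned rows and validates lengths", {
  ph <- full_fixture()
  aln <- to_alignment(ph)
  expect_length(aln, 2)
  expect_equal(unname(nchar(aln)), c(9, 9))
  expect_equal(names(aln), c("alcohol dehydrogenase",
                             "alcohol dehydrogenase B"))

  bad <- ph
  bad$root$children[[1]]$children[[2]]$sequences[[1]]$mol_seq <- "ACG"
  expect_error(to_alignment(bad), "unequal")
  expect_warning(empty <- to_alignment(make_t1()), "no aligned")
  expect_length(empty, 0)
})

test_that("element constructors validate their invariants", {
  expect_error(protein_domain(0, 10), "start")
  expect_error(protein_domain(10, 5), "start")
  expect_warning(taxonomy(rank = "imperial"), "vocabulary")
  expect_warning(mol_sequence(type = "dna", mol_seq = "ACGTX"), "alphabet")
  expect_error(branch_color(0, 0, 300), "255")
  expect_error(clade_events(speciations = -1), "non-negative")
  expect_error(mol_sequence(type = "protein", domain_architecture =
    list(length = 10, domains = list(protein_domain(2, 20)))), "exceeds")
})
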
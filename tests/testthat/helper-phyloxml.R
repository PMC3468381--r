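# phyloXML coverage fixture shared by the module and acceptance suites
full_fixture <- function() {
  dom <- protein_domain(5, 44, confidence = 7.0e-26, value = "CARD")
  seqA <- mol_sequence(type = "protein", symbol = "ADHX",
                       accession = "P81431", accession_source = "UniProtKB",
                       name = "alcohol dehydrogenase",
                       mol_seq = "MKAAVL-TD", is_aligned = TRUE,
                       domain_architecture = list(length = 50,
                                                  domains = list(dom)))
  seqB <- mol_sequence(type = "protein", symbol = "ADHB",
                       accession = "Q9SQ94", accession_source = "UniProtKB",
                       name = "alcohol dehydrogenase B",
                       mol_seq = "MKGLAV-SE", is_aligned = TRUE)
  taxA <- taxonomy(code = "OCTVU", scientific_name = "Octopus vulgaris",
                   rank = "species", common_names = "common octopus",
                   id = "6645", id_provider = "ncbi",
                   uri = phylo_uri("http://example.org/6645",
                                   desc = "taxon page"))
  tipA <- clade(name = "A", branch_length = 0.1, confidence = NULL,
                color = branch_color(0, 0, 255), width = 2,
                taxonomies = list(taxA), sequences = list(seqA),
                confidences = list(confidence_value(95, "bootstrap"),
                                   confidence_value(0.99, "posterior")),
                properties = list(phylo_property("1200", "NOAA:depth",
                                                 applies_to = "clade",
                                                 datatype = "xsd:integer",
                                                 unit = "METRIC:m")),
                uris = list(phylo_uri("http://example.org/A", type = "info")))
  tipB <- clade(name = "B", branch_length = 0.2, sequences = list(seqB),
                events = clade_events(speciations = 1, type = "speciation_or_duplication"),
                extras = "<custom xmlns=\"http://example.org/x\">kept</custom>")
  inner <- clade(name = "AB", branch_length = 0.05,
                 confidences = list(confidence_value(88, "bootstrap")),
                 events = clade_events(duplications = 1, losses = 0),
                 children = list(tipA, tipB))
  root <- clade(name = "root", children = list(inner,
                clade(name = "C", branch_length = 0.3)))
  phylogeny(root, rooted = TRUE, name = "coverage", id = "ph1",
            description = "one of every element type",
            confidences = list(confidence_value(1, "unknown")),
            properties = list(phylo_property("x", "ex:tag")),
            extras = "<date xmlns=\"http://example.org/y\">2005</date>")
}

expect_phylogeny_equal <- function(a, b) {
  expect_identical(a$name, b$name)
  expect_identical(a$id, b$id)
  expect_identical(a$description, b$description)
  expect_identical(a$rooted, b$rooted)
  expect_equal(length(a$confidences), length(b$confidences))
  expect_equal(a$confidences, b$confidences, ignore_attr = FALSE)
  expect_equal(a$properties, b$properties)
  cmp_clade <- function(x, y, where) {
    expect_identical(clade_name(x), clade_name(y), label = where)
    expect_equal(x$branch_length, y$branch_length, tolerance = 0,
                 label = paste(where, "branch"))
    expect_equal(x$confidences %||% list(), y$confidences %||% list(),
                 label = paste(where, "confidences"))
    expect_equal(x$color, y$color, label = paste(where, "color"))
    expect_equal(x$width, y$width, label = paste(where, "width"))
    expect_equal(x$taxonomies %||% list(), y$taxonomies %||% list(),
                 label = paste(where, "taxonomies"))
    expect_equal(x$sequences %||% list(), y$sequences %||% list(),
                 label = paste(where, "sequences"))
    expect_equal(x$events, y$events, label = paste(where, "events"))
    expect_equal(x$properties %||% list(), y$properties %||% list(),
                 label = paste(where, "properties"))
    expect_equal(x$uris %||% list(), y$uris %||% list(),
                 label = paste(where, "uris"))
    expect_identical(length(x$children), length(y$children), label = where)
    for (i in seq_along(x$children)) {
      cmp_clade(x$children[[i]], y$children[[i]], paste0(where, "/", i))
    }
  }
  cmp_clade(a$root, b$root, "root")
}
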
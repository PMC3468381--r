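Package: phylokit
Title: Unified Phylogenetic Tree Objects, I/O and Manipulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A format-independent object model for phylogenetic trees with a
    common set of inspection and manipulation methods (traversal and search,
    most recent common ancestor, patristic distances, monophyly tests,
    ladderizing, pruning, collapsing, outgroup and midpoint rerooting, random
    tree generation), parsers and serializers for the Newick, NEXUS and
    phyloXML formats unified behind a single read/parse/write/convert API,
    text and 2-D phylogram rendering, and a chi-square cumulative distribution
    function for likelihood-ratio tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    xml2
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
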
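# phylokit

Phylogenetic analyses routinely juggle trees in several incompatible file
formats: plain Newick strings from inference programs, NEXUS files with
TREES blocks and translate tables, and richly annotated phyloXML documents
from visualization and annotation pipelines. phylokit gives R users one
format-independent tree object and one API over all three, together with
the everyday inspection and manipulation operations of comparative
genomics workflows: traversal and search, most recent common ancestors,
patristic distances, monophyly tests, ladderizing, pruning and collapsing,
outgroup and midpoint rerooting, random tree generation, phylogram
rendering, and a chi-square CDF for likelihood-ratio tests of nested
models.

## The object model

A phylogeny is a `phylo_tree` — a rootedness flag plus a root `clade`.
Each clade holds an ordered list of child clades, nested recursively, with
an optional name, the length of the branch leading to it, a support value,
and cascading display attributes (colour, width). Trees need not be
bifurcating; polytomies are first-class. Every operation accepts either a
tree or a bare clade, so subtrees support the same methods as whole
phylogenies.

The quantities the package computes follow the standard definitions. The
depth of a clade is the sum of branch lengths from the root down to (and
including) the clade's own branch; the patristic distance between two
clades is

    d(a, b) = depth(a) + depth(b) - 2 * depth(mrca(a, b))

Midpoint rooting finds the terminal pair (p, q) maximizing d(p, q) and
places the root on the p–q path so that d(root, p) = d(root, q) =
d(p, q)/2. The likelihood-ratio test of nested models compares
2(lnL_alt − lnL_null) against the chi-square distribution whose CDF is
computed from the regularized lower incomplete gamma function
P(df/2, x/2).

## A worked example

```r
library(phylokit)

tr <- parse_newick("((A:1,B:2)X:3,(C:4,D:5)Y:6)R:0;")
count_terminals(tr)        # 4
total_branch_length(tr)    # 21
tree_distance(tr, "A", "D") # 15  (1 + 3 + 6 + 5)

draw_ascii(tr, column_width = 50)
#>              ____  A
#> _____________|
#> |            ________  B
#> |
#> |                        _________________  C
#> _________________________|
#>                          _____________________  D

serialize_newick(root_at_midpoint(tr))
#> "((C:4,D:5)Y:3,(A:1,B:2)X:6):0;"
```

The deepest tip pair is (B, D) at distance 16, so the midpoint root splits
the branch between Y and the old root into 3 + 3: afterwards both B and D
lie at depth 8. Total branch length (21) is conserved by rerooting.

Converting between formats is one call, and works for any registered
format pair:

```r
convert_trees("genetrees.nwk", "newick", "genetrees.xml", "phyloxml")

lrt(-1203.2, -1198.6, 2)
#> Likelihood-ratio test: statistic = 9.2, df = 2, p = 0.0100518
```

A command-line front end wrapping the same functions ships in
`inst/scripts/phylokit`:

```sh
phylokit stats tree.nwk newick          # "4 21 true"
phylokit reroot tree.nwk newick --all-nodes --out=all.nwk
phylokit convert tree.nwk newick tree.xml phyloxml
```

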
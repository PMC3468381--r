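---
title: "phylokit: tree model, file formats and algorithms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phylokit: tree model, file formats and algorithms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(phylokit)
```

## The tree model and its assumptions

phylokit represents a phylogeny as a `phylo_tree`: a rootedness flag, an
optional name and identifier, and a root `clade`. A clade is a node
together with everything below it — an ordered list of child clades,
nested recursively, with no auxiliary data structure underneath. The
model assumes the topology is a tree (each clade has a single parent,
no reticulation) but places no constraint on arity: polytomies are legal
everywhere, and strict bifurcation is a queryable property
(`is_bifurcating()`), not an invariant.

Three representational choices matter downstream:

* **Absent is not zero.** A branch length of `NULL` ("absent") is
  distinct from `0`. Absent lengths contribute 0 to depth and distance
  sums, but serializers never invent a `:0` for them, so a tree without
  branch lengths round-trips as such. Negative lengths — which
  neighbour-joining can produce — are accepted with a warning.
* **Depths include the root's branch.** The depth of a clade sums branch
  lengths from (and including) the root's own branch down to the clade's
  branch. A rooted tree serialized with a root branch therefore keeps
  consistent depths after a round-trip.
* **Display attributes cascade.** Colour and width apply to a clade and
  all its descendants until a descendant overrides them, as in phyloXML
  and the viewers that implement it. The cascade is kept virtual: no
  conversion materializes inherited colours onto children; resolution
  happens only at render time.

R's copy-on-modify semantics shape the API: operations that the
underlying algorithms describe as in-place (`ladderize`, `prune`,
`collapse_clade`, rerooting, `split_clade`) return the modified tree.
This is the same convention `ape` uses and removes a whole class of
aliasing bugs; `from_clade()` gets deep-copy isolation for free.

## Search, traversal and laziness

All search operations share one declarative matcher (`tree_query`): name
equality by default, attribute conjunctions, predicates, and element-class
restriction. Plain strings mean *exact* name equality; regular
expressions must be requested explicitly, because taxon names routinely
contain metacharacters and a silently-regex query would mismatch them.

Traversal is built on an explicit-stack iterator (`clade_iterator`) that
produces clades incrementally in preorder, postorder or level order.
Consuming k items does no more work than producing them requires, which
`find_any()` exploits to stop at the first hit; the iterator exposes a
visit counter so this is observable (and tested: taking one item from a
10,000-leaf tree touches a single node). `find_clades()` and
`find_elements()` are eager list wrappers over the iterator — R has no
idiomatic generator type, and for the file-level `parse_trees()` an eager
list is returned for the same reason.

`find_clades()` returns each clade that matches or *contains* a matching
annotation element; `find_elements()` returns the matching elements
themselves (a taxonomy, a confidence, …). On plain Newick/NEXUS trees,
where clades carry no annotation elements, the two coincide — the yielded
element type there is the clade itself, the least surprising reading of
the distinction.

## Manipulation semantics

* `ladderize()` sorts children at every node by descendant tip count,
  ascending by default (`reverse = TRUE` puts larger clades first). The
  sort is stable, so tied children keep their input order and the
  operation is a pure permutation of the tree.
* `prune()` removes a terminal. A non-root internal left with one child
  is collapsed by merging branch lengths (child absorbs parent's
  branch), conserving all remaining path lengths. When the *root* is
  left with a single child, that child is promoted to root — pruning one
  of two leaves yields a single-node tree rather than a degenerate
  chain. Elsewhere a root with a single child is permitted and
  serialized as-is.
* `collapse_clade()` deletes an internal node, splicing its children
  into its parent at its position with the deleted branch added to each
  child. This preserves every pairwise terminal distance; note it
  *increases* total branch length by (arity − 1) × branch, which is the
  price of distance conservation. `collapse_all()` iterates this until
  no (matching) non-root internal remains; with no query the result is a
  star whose tip branches equal the original root-to-tip depths.
* `split_clade()` adds n children named from the parent name plus a
  0-based counter ("X0", "X1", …; an unnamed parent yields bare "0",
  "1"), each with the given branch length.

## Rerooting

Both rerooting forms work by reversing the edges on the path from the old
root to the new root position; a former root left with a single child is
collapsed into it, summing branch lengths. These conserve the terminal
set, the full pairwise distance matrix, and total branch length — the
package's tests assert all three to 1e-9 on randomized trees.

For an outgroup, the new root is placed at the junction of the outgroup's
branch and its former parent: the parent becomes the root for a terminal
outgroup, the outgroup itself for an internal one, and the outgroup keeps
its branch length. Whether the root should instead bisect the outgroup's
branch is genuinely underdetermined by common usage, so it is an option
(`bisect = TRUE`, default off).

Midpoint rooting scans all terminal pairs for the maximal patristic
distance, then walks that path accumulating branch lengths until it
covers half the distance, and splits the branch it lands in. Ties between
maximal pairs are broken by lexicographic terminal-name order, making the
result deterministic; a midpoint falling exactly on a node yields a
zero-length branch rather than reusing the node. A tree with no branch
lengths at all cannot be midpoint-rooted and the error says to assign
unit branch lengths first.

## File formats

One tokenizer (quotes, `''` escapes, bracketed comments with one level of
nesting) backs two grammars:

* **Newick** — recursive descent; polytomies preserved; a bare numeric
  label on an *internal* clade is read as a support value (the common
  convention for bootstrap output) unless the dialect says otherwise;
  quoted labels and terminal labels are always names. Underscores are
  kept verbatim by default — round-trip fidelity beats the older
  underscore-to-space convention, which remains available as a dialect
  flag. Serialization quotes only when needed and prints every number as
  the shortest decimal that parses back to the same double. Newick
  carries no rootedness, so parsed trees default to unrooted.
  Any truncation of a valid statement is an error (fuzz-tested at every
  byte), never a silent partial tree.
* **NEXUS** — only the TREES block is interpreted; other blocks are
  skipped verbatim. TRANSLATE tokens are substituted into terminal
  labels, `[&R]`/`[&U]` set the rooted flag, keywords are
  case-insensitive, and a file without a TREES block yields an empty
  list rather than an error. The writer emits no translate table (valid
  per the standard, and round-trips cleanly).
* **phyloXML** — a full element model (taxonomy, molecular sequence with
  domain architecture, confidence, events, property, URI, colour, width)
  on top of `xml2`, with unrecognized elements preserved verbatim so
  third-party documents survive a convert cycle. `ProteinDomain`
  coordinates are 1-based inclusive, per the phyloXML specification —
  code touching them says so explicitly to avoid off-by-one against
  0-based conventions. Branch lengths are written as an attribute and
  accepted as attribute or child element. Because `xml2` reads a whole
  document, parsing is not streaming; memory scales with the document,
  not with the largest single phylogeny. Documents of the sizes this
  package targets (up to tens of thousands of tips) are well within
  reach; true streaming would require a SAX-style XML layer.

The `read`/`parse`/`write`/`convert` façade sits on a case-insensitive
format registry ("newick", "nexus", "phyloxml" always present;
`register_format()` adds or atomically replaces entries). Formats are
always named explicitly — file extensions are never sniffed. `read_tree`
demands exactly one tree and directs multi-tree files to `parse_trees`;
`write_trees` truncates existing files and never mutates its input.
Conversion narrows annotations to the common core (topology, names,
branch lengths, one confidence): phyloXML extras are dropped when
writing Newick/NEXUS, and a bare Newick confidence becomes a
`Confidence` element of type "unknown" on promotion.

## Visualization

`compute_layout()` maps each clade to (x, y): x is exactly the depth
mapping, terminals get consecutive integer rows in preorder, and each
internal row is the mean of its children's rows. `draw_ascii()` renders
that layout in monospace with one line per terminal name, tip extent
proportional to depth scaled into the column width; too-narrow widths
warn and auto-widen. The glyphs themselves are an internal detail — the
tests assert structure (name order, one name line per tip, monotone
columns), not exact art. `layout_segments()` exposes the branch and
connector segments as a data frame so any graphics layer can draw the
tree without this package depending on one. `tree_repr()` prints the
nested object hierarchy with only the attributes that are set; it backs
the `print` methods.

## Chi-square CDF

`cdf_chi2(x, df)` is the regularized lower incomplete gamma function
P(df/2, x/2), computed from first principles: a series expansion for
x < df + 1 and a Lentz-style continued fraction otherwise, with
log-gamma from a 9-term Lanczos approximation — a standard, accurate,
dependency-free construction. The supported domain is x ≥ 0,
1 ≤ df ≤ 200. Tests pin the df = 2 closed form 1 − exp(−x/2) to 1e-10
and agreement with an independent reference CDF to 1e-8 over
x ∈ [0, 50], df ∈ 1..10; the two branches agree through the crossover
region. `lrt()` wraps it for nested-model tests, clamping a negative
statistic (an optimizer artefact in truly nested fits) at 0 with a
warning.

## Randomized trees as test substrate

`random_tree()` grows a strictly bifurcating tree by repeatedly splitting
a uniformly chosen terminal until the requested tip count is reached,
then assigns the taxon names in random order; every generated branch gets
the same length (default 1), and a seed makes the result reproducible
(the global RNG state is restored afterwards). The test suites decorate
these trees with uniform random branch lengths in [0.05, 2] and, for the
serialization suites, derive "messy" variants — random polytomies via
collapsing, and randomly absent names and branch lengths — so the
round-trip properties are exercised on the awkward cases real files
contain. What these synthetic trees do *not* emulate: realistic
non-ultrametric rate variation, duplicated or unicode-heavy taxon names,
and malformed files beyond truncation — so the property tests certify the
algorithms and parsers, not robustness to arbitrarily hostile input.

Problem sizes in the shipped suites — 200 trees of 2–64 tips for
round-trips, 100 8-tip trees for the oracle comparisons (all tip pairs;
all tip subsets up to size 5), 100 trees of 4–16 tips for rerooting
invariants — were chosen to exercise every code path, including
polytomies and degenerate two-tip trees, while keeping the whole suite
fast enough to run habitually.

## Known limitations

* NeXML and NHX tags are out of scope (comments are skipped, not
  interpreted); no format sniffing; no inference, ancestral states or
  network structures.
* phyloXML parsing is DOM-based, not streaming (above).
* `is_monophyletic`/target resolution match clade arguments by
  structural identity; in trees with repeated identical subtrees the
  first preorder match wins — use names or queries for unambiguous
  targeting.
* Mixture chi-square corrections for boundary tests are not provided;
  `cdf_chi2` is the plain chi-square CDF.
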
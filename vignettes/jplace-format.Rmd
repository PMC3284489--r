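---
title: "The jplace placement format: model, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The jplace placement format: model, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jplacer)
```

## Phylogenetic placement and the document model

Phylogenetic placement maps each query sequence independently onto the
branches of a fixed reference tree, instead of rebuilding a tree de novo.
Because a short read often fits several branches almost equally well, a
single query yields a *collection* of candidate placements with
confidence values — a **pquery**. A jplace document bundles a reference
tree, an ordered field list, and a list of pqueries into one JSON object,
with placements indexed to branches through integer **edge numbers**
embedded in the Newick string in curly braces.

`jplacer` models this directly: `edge_tree` (a planar rooted tree whose
nodes carry optional label, branch length, verbatim `[...]` comment and
`{N}` edge number, plus a derived number-to-node index),
`jplace_pquery` (placement rows + names *or* named multiplicities), and
`jplace` (tree + fields + pqueries + version + metadata, the unit of
I/O).

## The edge-numbered Newick dialect

Standard Newick is extended with `{N}` after a node's other tokens. Curly
braces keep the numbers distinct from `[...]` annotations, which real
files use for supports or labels and which this package stores verbatim
and never interprets (nested brackets are rejected).

Parsing decisions, made where files in the wild disagree:

- **Token order.** After a node, `:length`, `[comment]` and `{number}`
  are accepted in any relative order — both `A:.01[e]{0}` and
  `D:.01{3}[g]` occur in published examples. Output always uses the fixed
  order `label:length{number}[comment]`, so writing is deterministic and
  `parse(write(t))` reproduces `t` field by field.
- **Whitespace** is ignored anywhere between tokens (`) {5}` occurs in
  real trees).
- **Branch lengths** must be non-negative: placement semantics
  (`distal_length` measured *within* an edge) presuppose it. Strict mode
  (default) rejects negatives; lenient mode warns.
- **Edge numbers** need not be contiguous and are never required for
  parsing; they must merely be unique. Trees without braces parse as
  plain Newick.

## The canonical numbering convention

For results from different programs to be comparable edge-by-edge, edges
are numbered 0..E−1 by a post-order traversal descending first-written
(left) subtrees first, with the top-level node receiving the final
number. The three-leaf tree `((A,B),C);` therefore numbers A=0, B=1, the
cherry 2, C=3 and the top-level slot 4. Where prose descriptions of the
convention are ambiguous, this worked three-leaf example is the fully
determined witness, and `canonical_edge_numbering()` implements exactly
it. The operation is idempotent and bijective onto 0..E−1; the test suite
verifies both by brute force against an independent stack-based traversal
on every planar tree shape with up to six leaves (65 shapes).
`renumber_jplace()` applies the convention to a whole document, remapping
every placement through the old-number → same-edge → new-number
correspondence so placements stay on the same physical branches.

## Fields and validation severities

`edge_num` is mandatory; `likelihood`, `like_weight_ratio`,
`distal_length`, `pendant_length` are the default maximum-likelihood
output, extended by `marginal_prob`/`post_prob` for posterior runs and by
`proximal_length` where a program optimizes it; parsimony runs use
`edge_num` + integer `parsimony`. Unrecognized fields are carried through
untyped and written back out — the format is extensible.

`validate_jplace()` returns issues rather than throwing, so one pass
reports everything. The severity split follows what is provably wrong
versus merely suspicious:

- **Errors** (structurally broken): version ≠ 3 in strict mode, a
  placement on an edge number the tree lacks, row length ≠ field count, a
  non-positive multiplicity, a non-integer parsimony score.
- **Warnings** (legal files can trigger them): `like_weight_ratio` or
  `post_prob` outside [0, 1]; a pquery's LWR sum above 1 + 1e−6 —
  programs may truncate low-probability placements, so sums *below* 1 are
  normal and small overshoots are rounding, which is why this is not an
  error; `distal_length` exceeding its edge's branch length; a positive
  log likelihood (placements are scored on masked alignments, so values
  *closer to zero* than the reference likelihood are expected, but
  positive ones indicate a unit mistake); version ≠ 3 in lenient mode
  (older files exist and remain readable).

Completeness of equally-parsimonious placements is a producer obligation
that cannot be checked without re-running placement; it is documented,
not validated.

Two text-level conveniences: `lenient_text = TRUE` normalizes
typographic quotes and the Unicode minus to ASCII before JSON parsing
(text copied from typeset documents is otherwise unparseable); output is
always strict ASCII JSON with the top-level key order `tree, placements,
metadata, version, fields` and shortest round-trip numbers, with
real-valued fields always keeping a decimal point (`1.0`, never `1`).

## Operations

*Subset* keeps pqueries intersecting a name set or touching given edges,
intact and in order. *Merge* requires planar-identical trees (topology,
child order, labels, edge numbers; branch lengths exact by default, a
tolerance flag loosens it — exactness is merge safety), identical field
lists and version, then concatenates; pquery identity is undefined by the
format, so nothing is deduplicated unless `dedupe = TRUE`, which combines
pqueries with identical name sets *and* identical placement rows, summing
multiplicities. *Best placement* maximizes LWR, posterior probability or
likelihood, or minimizes parsimony, breaking ties by lowest edge number
then first occurrence, so extraction is deterministic.

*Tabular export* assigns a dense 0-based `placement_id` to every
placement row in document order; the name table maps every placement_id
to each of its pquery's names — the full cross product — because ids
attach to placements while names attach to pqueries. Names from `n`
lists get multiplicity 1.

*Grafting* renders the pendant-branch picture of a placement: the edge is
split `distal_length` from its distal (child-side) node and a new leaf
hangs on a `pendant_length` branch. Only the best placement per pquery is
grafted: expanding every uncertain placement into a pendant would make
pendants from uncertainty indistinguishable from pendants from distinct
queries, which is precisely the confusion the list-based format exists to
avoid. Multiple insertions on one edge are ordered by distal length and
chained, so reference branch length is conserved exactly; the output tree
is plain Newick (numbers and comments dropped). Out-of-range distal
lengths are clamped with a warning (error in strict mode), mirroring the
validator. A placement on the top-level slot (which has no branch length)
attaches at the node itself in lenient mode.

## The synthetic generator

`generate_document()` emulates the statistical shape of real placement
output for property testing; its defaults are fixed once and are not
tuning knobs. Reference trees grow by sequential random attachment
(each new leaf splits a uniformly chosen edge) with Exp(mean 0.1) branch
lengths — the scale of typical reference trees; the top-level node has no
length and accordingly hosts no placements. Per pquery, placements fall
on distinct edges; LWRs are a Dirichlet(shape 1.5) draw scaled by a
coverage drawn in [0.9, 0.999], so sums stay strictly below 1 even after
6-digit rounding (by construction, not by filtering); log likelihoods are
`C + log w` for a common total `C` in [−5000, −500], making their order
agree with the LWRs; `distal_length` is uniform within its edge (capped
at the branch length after rounding) and `pendant_length` is
Exp(mean 0.05) plus a floor of 1e−6; parsimony pqueries share one integer
score across their placements, since equally parsimonious placements are
reported together. A configurable fraction of pqueries gets named
multiplicities (uniform in [0.5, 20]); the rest get 1–3 names. The same
seed yields byte-identical documents.

What passing property tests shows — and does not. Generated documents
exercise both name representations, all three field profiles,
non-contiguous edge usage and empty documents, so round-trip exactness,
validation cleanliness, the table row-count identities and graft length
conservation are tested over that whole envelope (200 seeded documents in
the acceptance suite, with trees of 3–12 leaves and up to 8 pqueries —
sizes chosen to keep the property batch exhaustive per-document rather
than large). They do not cover quoted Newick labels, multifurcating
reference trees beyond what parsing allows, pathological metadata, or
files produced by buggy tools; the validator, not the generator, is the
line of defense there.

## Numerical choices and limitations

Numbers are emitted with the shortest decimal representation that
round-trips through a double, so `parse(write(d))` is `identical(d)`
exactly, not approximately. Tree compatibility defaults to exact
branch-length equality because merging is only safe on the same tree;
the tolerance flag exists for trees that went through different
serializers. Multiplicities printed as integers (`2`) stay plain on
output; values of real-valued placement fields always keep a decimal
point.

Known limitations: quoted Newick labels (single-quote dialect) are not
supported; unrooted-tree canonicalization, re-rooting and branch-length
optimization are out of scope, as are downstream comparative statistics
and visualization; version acceptance covers integers 1–3 (warning when
not 3) — there is no migration from the older idiosyncratic tabular
formats.
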
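# jplacer

Read, validate and manipulate **jplace** files — the JSON-based standard
for storing *phylogenetic placements*, i.e. mappings of query sequences
(typically short environmental reads) onto the branches of a fixed
reference phylogeny, as produced by tools such as pplacer and EPA.

A jplace document is a single JSON object with five top-level keys:

- `tree` — the reference tree in an extended Newick dialect where every
  edge carries an integer number in curly braces (`B:0.09{1}`) and may
  carry a verbatim comment in square brackets (`[g]`);
- `fields` — the ordered column names for placement rows, e.g.
  `edge_num`, `likelihood`, `like_weight_ratio` (LWR, the ratio of a
  placement's likelihood to the summed likelihoods of that query's
  alternatives), `distal_length`, `pendant_length`;
- `placements` — a list of *pqueries* ("placed queries"): each holds the
  candidate placements of one query, expressing placement uncertainty,
  plus either a name list (`n`) or *named multiplicities* (`nm`, pairs of
  a name and a positive count or transformed count);
- `version` (mandatory, canonically 3) and `metadata` (optional, e.g. the
  generating command line).

`jplacer` implements this format end to end: parsing and writing both the
Newick dialect and the JSON document, semantic validation, canonical
post-order edge renumbering, subsetting/merging of placement collections,
best-placement extraction, multiplicity accounting, relational
(two-table) export, grafting of placements as pendant branches, a seeded
synthetic-document generator, and a command-line interface.

## Worked example

The package ships a tiny document with two pqueries on a three-leaf
reference tree (`inst/extdata/small_example.jplace`):

```r
library(jplacer)
path <- system.file("extdata", "small_example.jplace", package = "jplacer")
doc <- read_jplace(path)
doc
#> jplace document (version 3)
#>   tree: 3 leaves, 5 numbered edges
#>   fields: edge_num, likelihood, like_weight_ratio, distal_length, pendant_length
#>   pqueries: 2 (3 placements)

validate_jplace(doc, strict = TRUE)   # zero rows: fully conformant
#> [1] severity path     message
#> <0 rows> (or 0-length row.names)
```

The first pquery (`fragment1`/`fragment2`) has two candidate placements;
the one on edge 1 carries most of the likelihood weight (LWR 0.777385
versus 0.107065 on edge 0), so it wins best-placement extraction:

```r
best_placement(doc$pqueries[[1]], doc$fields, "like_weight_ratio")[[1]]
#> [1] 1
```

Relational export assigns a dense `placement_id` to every placement row
and cross-products each pquery's names with its placements — here 3
placement rows and 6 name rows; names from a plain `n` list get
multiplicity 1, `nm` pairs keep theirs (1.5 and 2, totalling 3.5):

```r
to_tables(doc)$names
#>   placement_id      name multiplicity
#> 1            0 fragment1          1.0
#> 2            0 fragment2          1.0
#> 3            1 fragment1          1.0
#> 4            1 fragment2          1.0
#> 5            2 fragment3          1.5
#> 6            2 fragment4          2.0
```

Grafting renders each pquery's best placement as a pendant branch: the
placement edge is split `distal_length` above its child-side node and a
new leaf hangs on a `pendant_length` branch. Reference branch lengths are
conserved, so the grafted tree is the reference total (1.49) plus the two
pendant lengths:

```r
g <- graft_jplace(doc)
write_newick_edges(g)
#> (((A:0.2,(B:0.004132,fragment1:0.0006):0.085868):0.003555,fragment3:6e-06):0.696445,C:0.5);
```

## Command line

The installed script `inst/exec/jplace` exposes the same operations:

```sh
jplace validate my.jplace                 # exit 1 if semantic ERRORs
jplace merge a.jplace b.jplace -o ab.jplace
jplace subset --names frag1,frag2 a.jplace -o sub.jplace
jplace to-csv a.jplace -o tables          # tables_placements.csv, tables_names.csv
jplace renumber a.jplace -o canon.jplace  # canonical numbering + remap
jplace graft a.jplace -o grafted.nwk
jplace generate --seed 7 --n-leaves 20 --n-pqueries 50 -o sim.jplace
```

Every file the CLI writes records the command line under
`metadata$invocation` for reproducibility.

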
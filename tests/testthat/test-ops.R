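test_that("subsetting keeps intact pqueries matched by name or by edge", {
  doc <- example_doc()
  by_name <- subset_jplace(doc, names = "fragment3")
  expect_length(by_name$pqueries, 1)
  expect_identical(by_name$pqueries[[1]], doc$pqueries[[2]])
  expect_true(trees_compatible(by_name$tree, doc$tree))

  by_edge <- subset_jplace(doc, edges = 0L)
  expect_length(by_edge$pqueries, 1)
  expect_identical(by_edge$pqueries[[1]], doc$pqueries[[1]])

  none <- subset_jplace(doc, names = character(0))
  expect_length(none$pqueries, 0)
  expect_true(trees_compatible(none$tree, doc$tree))

  all_names <- unlist(lapply(doc$pqueries, pquery_names))
  expect_identical(subset_jplace(doc, names = all_names), doc)
  expect_error(subset_jplace(doc), class = "jplace_usage_error")
})

test_that("merging concatenates pqueries and enforces its preconditions", {
  doc <- example_doc()
  m <- merge_jplace(list(doc, doc))
  expect_length(m$pqueries, 4)
  expect_identical(m$pqueries[3:4], doc$pqueries)
  expect_length(m$metadata$merged, 2)
  expect_identical(merge_jplace(list(doc)), doc)

  refielded <- doc
  refielded$fields <- rev(doc$fields)
  expect_error(merge_jplace(list(doc, refielded)), "fields",
               class = "jplace_merge_error")

  retree <- doc
  retree$tree <- parse_newick_edges(
    "((B:0.09{1},A:0.2{0}):0.7{2},C:0.5{3}){4};")
  expect_error(merge_jplace(list(doc, retree)), "incompatible",
               class = "jplace_merge_error")

  rever <- doc
  rever$version <- 2L
  expect_error(merge_jplace(list(doc, rever)), "version",
               class = "jplace_merge_error")
})

test_that("partitioning by name and re-merging recovers the pquery multiset", {
  doc <- example_doc()
  part1 <- subset_jplace(doc, names = c("fragment1", "fragment2"))
  part2 <- subset_jplace(doc, names = c("fragment3", "fragment4"))
  merged <- merge_jplace(list(part1, part2))
  expect_identical(merged$pqueries, doc$pqueries)
  expect_identical(length(merged$pqueries), length(doc$pqueries))
  expect_identical(sum(vapply(merged$pqueries, total_multiplicity,
                              double(1))),
                   sum(vapply(doc$pqueries, total_multiplicity,
                              double(1))))
})

test_that("merge with dedupe combines identical pqueries, summing multiplicity", {
  doc <- example_doc()
  m <- merge_jplace(list(doc, doc), dedupe = TRUE)
  expect_length(m$pqueries, 2)
  expect_identical(total_multiplicity(m$pqueries[[1]]), 4)    # 2 + 2 names
  expect_identical(total_multiplicity(m$pqueries[[2]]), 7)    # 3.5 + 3.5
})

test_that("best placement maximizes or minimizes its criterion with stable ties", {
  doc <- example_doc()
  best1 <- best_placement(doc$pqueries[[1]], doc$fields,
                          "like_weight_ratio")
  expect_identical(best1[[1]], 1)  # 0.777385 on edge 1 beats 0.107065
  # the higher (closer to zero) log likelihood is the same placement
  expect_identical(best_placement(doc$pqueries[[1]], doc$fields,
                                  "likelihood"), best1)
  for (crit in c("like_weight_ratio", "likelihood")) {
    expect_identical(best_placement(doc$pqueries[[2]], doc$fields, crit),
                     doc$pqueries[[2]]$placements[[1]])
  }
  expect_error(best_placement(doc$pqueries[[1]], doc$fields, "post_prob"),
               class = "jplace_usage_error")

  # equal scores on edges 5 and 3: lowest edge number wins
  tied <- pquery(list(list(5, 10), list(3, 10)), names = "q")
  expect_identical(best_placement(tied, c("edge_num", "parsimony"),
                                  "parsimony")[[1]], 3)
  # parsimony minimizes
  pars <- pquery(list(list(0, 7), list(1, 4)), names = "q")
  expect_identical(best_placement(pars, c("edge_num", "parsimony"),
                                  "parsimony")[[1]], 1)
})

test_that("multiplicity accounting counts names or sums nm values", {
  doc <- example_doc()
  expect_identical(total_multiplicity(doc$pqueries[[1]]), 2L)
  expect_identical(total_multiplicity(doc$pqueries[[2]]), 3.5)
  expect_identical(
    total_multiplicity(pquery(list(list(0)), multiplicities = data.frame(
      name = "x", multiplicity = 1.0))), 1.0)

  nm <- names_to_multiplicities(doc$pqueries[[1]])
  expect_identical(nm$multiplicities$name, c("fragment1", "fragment2"))
  expect_identical(nm$multiplicities$multiplicity, c(1, 1))
  expect_identical(total_multiplicity(nm), 2)
  expect_identical(
    names_to_multiplicities(pquery(list(list(0)), names = "a"),
                            transform = sqrt)$multiplicities$multiplicity,
    1.0)
  expect_error(names_to_multiplicities(nm), class = "jplace_usage_error")
})

test_that("relational export assigns dense ids and cross-products names", {
  doc <- example_doc()
  tabs <- to_tables(doc)
  expect_identical(nrow(tabs$placements), 3L)
  expect_identical(tabs$placements$placement_id, 0:2)
  expect_identical(colnames(tabs$placements),
                   c("placement_id", doc$fields))
  expect_identical(tabs$placements$edge_num, c(1, 0, 2))

  expect_identical(nrow(tabs$names), 6L)
  expect_identical(tabs$names$placement_id, c(0L, 0L, 1L, 1L, 2L, 2L))
  expect_identical(tabs$names$name,
                   c("fragment1", "fragment2", "fragment1", "fragment2",
                     "fragment3", "fragment4"))
  expect_identical(tabs$names$multiplicity, c(1, 1, 1, 1, 1.5, 2))

  empty <- to_tables(jplace_document(parse_newick_edges("A{0};"),
                                     c("edge_num", "likelihood")))
  expect_identical(nrow(empty$placements), 0L)
  expect_identical(colnames(empty$placements),
                   c("placement_id", "edge_num", "likelihood"))
  expect_identical(colnames(empty$names),
                   c("placement_id", "name", "multiplicity"))
})

test_that("grafting inserts one pendant branch per pquery and conserves length", {
  doc <- example_doc()
  g <- graft_jplace(doc)
  expect_identical(n_leaves(g$root), 5L)  # 3 reference + 2 pqueries
  expect_equal(tree_total_length(g),
               tree_total_length(doc$tree) + 0.0006 + 0.000006)
  expect_identical(edge_numbers(g), integer(0))
  labs <- leaf_labels(g)
  expect_true(all(c("A", "B", "C", "fragment1", "fragment3") %in% labs))
  joined <- graft_jplace(doc, name_policy = "join", sep = "|")
  expect_true("fragment1|fragment2" %in% leaf_labels(joined))

  # zero pqueries: the reference tree minus numbering
  empty <- subset_jplace(doc, names = character(0))
  g0 <- graft_jplace(empty)
  expect_identical(
    write_newick_edges(g0),
    write_newick_edges(doc$tree, include_edge_numbers = FALSE,
                       include_comments = FALSE))

  # distal_length 0 attaches at the distal node itself
  at_node <- doc
  at_node$pqueries <- doc$pqueries[2]
  at_node$pqueries[[1]]$placements[[1]][[4]] <- 0
  gd <- graft_jplace(at_node)
  expect_equal(tree_total_length(gd),
               tree_total_length(doc$tree) + 0.000006)
  # the split point sits at the bottom of edge 2: its lower segment is 0
  expect_match(write_newick_edges(gd), "):0,", fixed = TRUE)

  # out-of-range distal_length: clamped with a warning, error when strict
  far <- doc
  far$pqueries[[1]]$placements[[1]][[4]] <- 0.5
  expect_warning(gf <- graft_jplace(far), "clamped")
  expect_equal(tree_total_length(gf),
               tree_total_length(doc$tree) + 0.0006 + 0.000006)
  expect_error(suppressWarnings(graft_jplace(far, strict = TRUE)),
               class = "jplace_usage_error")

  # required fields must be present
  pars <- jplace_document(doc$tree, c("edge_num", "parsimony"),
                          list(pquery(list(list(0, 3)), names = "q")))
  expect_error(graft_jplace(pars), class = "jplace_usage_error")
})

test_that("canonical renumbering remaps placements onto the same physical edges", {
  # same planar tree, scrambled numbering: A=10, B=7, internal=3, C=0, top=12
  txt <- '{"tree": "((A:0.2{10},B:0.09{7}):0.7{3},C:0.5{0}){12};",
           "fields": ["edge_num", "distal_length"],
           "placements": [
             {"p": [[10, 0.1], [0, 0.2]], "n": ["on_A_and_C"]},
             {"p": [[3, 0.5]], "n": ["on_internal"]}],
           "version": 3}'
  doc <- parse_jplace(txt)
  out <- renumber_jplace(doc)
  expect_identical(edge_numbers(out$tree), 0:4)
  expect_identical(edge_lookup(out$tree, 0)$label, "A")
  expect_identical(out$pqueries[[1]]$placements[[1]][[1]], 0)  # A: 10 -> 0
  expect_identical(out$pqueries[[1]]$placements[[2]][[1]], 3)  # C: 0 -> 3
  expect_identical(out$pqueries[[2]]$placements[[1]][[1]], 2)  # int: 3 -> 2
  # idempotent on an already-canonical document
  expect_identical(renumber_jplace(out), out)
  # values other than edge_num are untouched
  expect_identical(out$pqueries[[1]]$placements[[1]][[2]], 0.1)
})
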
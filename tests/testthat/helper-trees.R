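# Shared fixtures and small independent oracles for the test suite.

example_path <- function() {
  system.file("extdata", "small_example.jplace", package = "jplacer")
}

typeset_example_path <- function() {
  system.file("extdata", "small_example_typeset.jplace", package = "jplacer")
}

example_doc <- function() read_jplace(example_path())

example_tree_text <- "((A:0.2{0},B:0.09{1}):0.7{2},C:0.5{3}){4};"
mixed_order_tree_text <-
  "((A:.01[e]{0}, B:.01{1})D:.01{3}[g], C:.01{4}[h]) {5};"

# Every planar (child-order-sensitive) rooted binary tree shape with n
# leaves, leaves labeled t1..tn left to right. Counts follow the Catalan
# numbers: 1, 1, 2, 5, 14, 42 for n = 1..6.
all_tree_shapes <- function(n) {
  shapes <- function(k) {
    if (k == 1L) return(list(tree_node(label = "t")))
    out <- list()
    for (i in seq_len(k - 1L)) {
      for (l in shapes(i)) {
        for (r in shapes(k - i)) {
          out[[length(out) + 1L]] <- tree_node(children = list(l, r))
        }
      }
    }
    out
  }
  lapply(shapes(n), function(root) {
    k <- 0L
    relabel <- function(node) {
      if (length(node$children) == 0L) {
        k <<- k + 1L
        node$label <- paste0("t", k)
      } else {
        node$children <- lapply(node$children, relabel)
      }
      node
    }
    edge_tree(relabel(root))
  })
}

# Independent post-order numbering oracle: an explicit-stack traversal,
# structurally different from the package's recursive implementation.
postorder_numbers_oracle <- function(tree) {
  out <- character(0)
  stack <- list(list(node = tree$root, path = "r", expanded = FALSE))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (top$expanded || length(top$node$children) == 0L) {
      out <- c(out, top$path)
    } else {
      top$expanded <- TRUE
      stack[[length(stack) + 1L]] <- top
      for (i in rev(seq_along(top$node$children))) {
        stack[[length(stack) + 1L]] <-
          list(node = top$node$children[[i]],
               path = paste0(top$path, ".", i), expanded = FALSE)
      }
    }
  }
  stats::setNames(seq_along(out) - 1L, out)
}

# Node path -> assigned edge number, for comparison with the oracle.
numbering_by_path <- function(tree) {
  out <- integer(0)
  walk <- function(node, path) {
    for (i in seq_along(node$children)) {
      walk(node$children[[i]], paste0(path, ".", i))
    }
    if (!is.null(node$edge_number)) {
      out[[path]] <<- node$edge_number
    }
  }
  walk(tree$root, "r")
  out
}

# Mix of generator configurations exercising all field profiles and both
# name representations.
synthetic_configs <- function(n, base_seed) {
  profiles <- c("ML", "posterior", "parsimony")
  lapply(seq_len(n), function(i) {
    generator_config(
      n_leaves = 3L + (i %% 10L),
      n_pqueries = i %% 9L,
      max_placements_per_pquery = 1L + (i %% 4L),
      field_profile = profiles[1L + (i %% 3L)],
      nm_fraction = c(0, 0.5, 1)[1L + (i %% 3L)],
      seed = base_seed + i
    )
  })
}
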
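# Seeded generator of random reference trees and jplace documents with the
# statistical structure the format assumes; used for property tests and as
# the CLI `generate` subcommand.

#' Configuration for the synthetic document generator
#'
#' @param n_leaves Number of leaves in the reference tree (>= 1).
#' @param n_pqueries Number of pqueries to generate (>= 0).
#' @param max_placements_per_pquery Upper bound on placements per pquery
#'   (>= 1); the actual count is drawn uniformly from 1..max.
#' @param field_profile `"ML"` (edge_num, likelihood, like_weight_ratio,
#'   distal_length, pendant_length — the default output of a maximum
#'   likelihood placement run), `"posterior"` (ML plus marginal_prob and
#'   post_prob) or `"parsimony"` (edge_num, parsimony).
#' @param nm_fraction Fraction of pqueries carrying named multiplicities
#'   instead of name lists, in [0, 1].
#' @param seed Integer seed; the same configuration always produces
#'   byte-identical output.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_leaves = 10L, n_pqueries = 20L,
                             max_placements_per_pquery = 3L,
                             field_profile = c("ML", "posterior",
                                               "parsimony"),
                             nm_fraction = 0.3, seed = 1L) {
  field_profile <- match.arg(field_profile)
  stopifnot(n_leaves >= 1L, n_pqueries >= 0L,
            max_placements_per_pquery >= 1L,
            nm_fraction >= 0, nm_fraction <= 1)
  structure(list(n_leaves = as.integer(n_leaves),
                 n_pqueries = as.integer(n_pqueries),
                 max_placements_per_pquery =
                   as.integer(max_placements_per_pquery),
                 field_profile = field_profile,
                 nm_fraction = nm_fraction,
                 seed = as.integer(seed)),
            class = "generator_config")
}

profile_fields <- function(profile) {
  switch(profile,
         ML = c("edge_num", "likelihood", "like_weight_ratio",
                "distal_length", "pendant_length"),
         posterior = c("edge_num", "likelihood", "like_weight_ratio",
                       "distal_length", "pendant_length", "marginal_prob",
                       "post_prob"),
         parsimony = c("edge_num", "parsimony"))
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a random reference tree
#'
#' Builds a rooted binary tree by sequential random attachment: starting
#' from a two-leaf cherry, each new leaf splits a uniformly chosen existing
#' edge. Branch lengths are exponential with mean 0.1 (the scale typical of
#' reference trees); the top-level node carries no branch length. Canonical
#' post-order edge numbering is applied, so a tree with n leaves carries
#' 2n - 1 numbered edges (counting the top-level slot). Deterministic under
#' the configuration seed.
#'
#' @param config A [generator_config()].
#' @return An [edge_tree()].
#' @export
generate_tree <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n <- config$n_leaves
    bl <- function() stats::rexp(1, rate = 10)
    if (n == 1L) {
      return(canonical_edge_numbering(edge_tree(tree_node(label = "L1"))))
    }
    root <- tree_node(children = list(
      tree_node(label = "L1", branch_length = bl()),
      tree_node(label = "L2", branch_length = bl())
    ))
    # paths to every node below the root (each one an attachable edge)
    node_paths <- function(node, path) {
      out <- if (length(path) > 0L) list(path) else list()
      for (i in seq_along(node$children)) {
        out <- c(out, node_paths(node$children[[i]], c(path, i)))
      }
      out
    }
    get_at <- function(node, path) {
      for (i in path) node <- node$children[[i]]
      node
    }
    set_at <- function(node, path, value) {
      if (length(path) == 0L) return(value)
      node$children[[path[1]]] <- set_at(node$children[[path[1]]],
                                         path[-1], value)
      node
    }
    for (k in seq_len(n - 2L) + 2L) {
      paths <- node_paths(root, integer(0))
      target <- paths[[sample.int(length(paths), 1L)]]
      old <- get_at(root, target)
      split_at <- stats::runif(1) * old$branch_length
      upper <- old$branch_length - split_at
      old$branch_length <- split_at
      new_leaf <- tree_node(label = paste0("L", k), branch_length = bl())
      root <- set_at(root, target,
                     tree_node(children = list(old, new_leaf),
                               branch_length = upper))
    }
    canonical_edge_numbering(edge_tree(root))
  })
}

#' Generate a random jplace document
#'
#' Emulates the value semantics of real placement output on a
#' [generate_tree()] reference: each pquery gets placements on distinct
#' edges; likelihood weight ratios come from a Dirichlet draw scaled below
#' 1 (placement programs may truncate low-probability placements, so sums
#' under 1 are normal); log likelihoods are negative and ordered
#' consistently with the weight ratios; `distal_length` is uniform within
#' each edge's branch length and `pendant_length` is exponential; the
#' parsimony profile gives all of a pquery's placements an equal integer
#' score (equally parsimonious placements are reported together). A
#' configured fraction of pqueries carries named multiplicities, the rest
#' name lists. Every generated document validates with zero errors.
#'
#' @param config A [generator_config()].
#' @return A [jplace_document()].
#' @export
generate_document <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  tree <- generate_tree(config)
  fields <- profile_fields(config$field_profile)
  # candidate edges must have a branch length (the top-level slot has none)
  usable <- Filter(function(en) {
    !is.null(edge_lookup(tree, en)$branch_length)
  }, edge_numbers(tree))
  if (config$n_pqueries > 0L && length(usable) == 0L) {
    stop_jplace("tree has no edges with branch lengths to place on; ",
                "use n_leaves >= 2", class = "jplace_usage_error")
  }
  with_seed(config$seed + 104729L, {
    pqueries <- lapply(seq_len(config$n_pqueries), function(q) {
      k <- sample.int(min(config$max_placements_per_pquery,
                          length(usable)), 1L)
      edges <- usable[sample.int(length(usable), k)]
      rows <- switch(
        config$field_profile,
        ML = ml_rows(tree, edges),
        posterior = posterior_rows(tree, edges),
        parsimony = parsimony_rows(edges)
      )
      nms <- paste0("query_", q, letters[seq_len(sample.int(3L, 1L))])
      if (stats::runif(1) < config$nm_fraction) {
        pquery(rows, multiplicities = data.frame(
          name = nms,
          multiplicity = round(stats::runif(length(nms), 0.5, 20), 3),
          stringsAsFactors = FALSE
        ))
      } else {
        pquery(rows, names = nms)
      }
    })
    jplace_document(
      tree = tree, fields = fields, pqueries = pqueries, version = 3L,
      metadata = list(invocation = paste(
        "jplacer generate --seed", config$seed,
        "--n-leaves", config$n_leaves,
        "--n-pqueries", config$n_pqueries,
        "--profile", config$field_profile
      ))
    )
  })
}

# Dirichlet weights scaled by a coverage just under 1 (low-probability
# placements are assumed truncated away), plus log likelihoods whose order
# matches the weights: ll_i = C + log w_i for a common masked-alignment
# total C < 0.
lwr_and_likelihood <- function(k) {
  w <- stats::rgamma(k, shape = 1.5)
  w <- w / sum(w)
  coverage <- stats::runif(1, 0.9, 0.999)
  total_ll <- -stats::runif(1, 500, 5000)
  list(lwr = round(w * coverage, 6), ll = round(total_ll + log(w), 4))
}

attach_lengths <- function(tree, edges) {
  bls <- vapply(edges, function(en) edge_lookup(tree, en)$branch_length,
                double(1))
  list(distal = pmin(round(stats::runif(length(edges), 0, bls), 6), bls),
       pendant = round(stats::rexp(length(edges), rate = 20) + 1e-6, 6))
}

ml_rows <- function(tree, edges) {
  s <- lwr_and_likelihood(length(edges))
  a <- attach_lengths(tree, edges)
  lapply(seq_along(edges), function(i) {
    list(as.double(edges[i]), s$ll[i], s$lwr[i], a$distal[i], a$pendant[i])
  })
}

posterior_rows <- function(tree, edges) {
  s <- lwr_and_likelihood(length(edges))
  a <- attach_lengths(tree, edges)
  pp <- s$lwr * stats::runif(1, 0.9, 0.999)  # posterior mass, summing <= 1
  marg <- round(stats::runif(length(edges)), 6)
  lapply(seq_along(edges), function(i) {
    list(as.double(edges[i]), s$ll[i], s$lwr[i], a$distal[i], a$pendant[i],
         marg[i], round(pp[i], 6))
  })
}

parsimony_rows <- function(edges) {
  score <- as.double(sample.int(40L, 1L))  # equal across the pquery
  lapply(edges, function(en) list(as.double(en), score))
}
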
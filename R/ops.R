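# Manipulations the list-based jplace layout makes cheap: subsetting,
# merging, best-placement extraction, multiplicity accounting, relational
# export and pendant-branch grafting.

row_edge <- function(row, fields) {
  v <- placement_value(row, fields, "edge_num")
  if (is.numeric(v)) as.integer(v) else NA_integer_
}

#' Subset the pqueries of a document
#'
#' Retains every pquery whose name set intersects `names`, or that has at
#' least one placement on an edge in `edges` (a pquery matching either
#' criterion is kept intact). The tree, fields, version and metadata are
#' unchanged; pquery order is preserved. An empty result is legal.
#'
#' @param doc A [jplace_document()].
#' @param names Character vector of query names to keep, or `NULL`.
#' @param edges Integer vector of edge numbers to keep, or `NULL`.
#' @return A new `jplace` document.
#' @export
subset_jplace <- function(doc, names = NULL, edges = NULL) {
  stopifnot(inherits(doc, "jplace"))
  if (is.null(names) && is.null(edges)) {
    stop_jplace("supply 'names' and/or 'edges' to subset on",
                class = "jplace_usage_error")
  }
  keep <- vapply(doc$pqueries, function(pq) {
    hit <- FALSE
    if (!is.null(names)) {
      hit <- hit || any(pquery_names(pq) %in% names)
    }
    if (!is.null(edges)) {
      pe <- vapply(pq$placements, row_edge, integer(1), fields = doc$fields)
      hit <- hit || any(pe %in% as.integer(edges))
    }
    hit
  }, logical(1))
  doc$pqueries <- doc$pqueries[keep]
  doc
}

#' Merge jplace documents sharing a reference tree
#'
#' All inputs must have compatible trees (identical planar topology, labels,
#' edge numbers and branch lengths, see [trees_compatible()]), identical
#' field lists and the same version. Pquery lists are concatenated in input
#' order. The inputs' metadata objects are collected under a `merged` record
#' in the output metadata. Pqueries appearing in several inputs under the
#' same name are not deduplicated unless `dedupe = TRUE`, in which case
#' pqueries with identical name sets and identical placement rows are
#' combined with their multiplicities summed.
#'
#' @param docs List of [jplace_document()] objects (at least one).
#' @param tolerance Branch-length tolerance for tree compatibility.
#' @param dedupe Combine identically named, identically placed pqueries.
#' @return A merged `jplace` document.
#' @export
merge_jplace <- function(docs, tolerance = 0, dedupe = FALSE) {
  stopifnot(is.list(docs), length(docs) >= 1L)
  for (d in docs) stopifnot(inherits(d, "jplace"))
  first <- docs[[1]]
  for (i in seq_along(docs)[-1]) {
    if (!trees_compatible(first$tree, docs[[i]]$tree,
                          tolerance = tolerance)) {
      stop_jplace("document ", i, " has a reference tree incompatible ",
                  "with document 1 (planar topology, labels, edge numbers ",
                  "and branch lengths must match)",
                  class = "jplace_merge_error")
    }
    if (!identical(first$fields, docs[[i]]$fields)) {
      stop_jplace("document ", i, " has fields [",
                  paste(docs[[i]]$fields, collapse = ", "),
                  "] but document 1 has [",
                  paste(first$fields, collapse = ", "), "]",
                  class = "jplace_merge_error")
    }
    if (!identical(first$version, docs[[i]]$version)) {
      stop_jplace("document ", i, " has version ", docs[[i]]$version,
                  " but document 1 has version ", first$version,
                  class = "jplace_merge_error")
    }
  }
  pqueries <- do.call(c, lapply(docs, function(d) d$pqueries))
  if (dedupe) pqueries <- dedupe_pqueries(pqueries)
  metadata <- if (length(docs) == 1L) {
    first$metadata
  } else {
    list(merged = lapply(docs, function(d) {
      if (is.null(d$metadata)) list() else d$metadata
    }))
  }
  jplace_document(tree = first$tree, fields = first$fields,
                  pqueries = pqueries, version = first$version,
                  metadata = metadata, extra = first$extra)
}

dedupe_pqueries <- function(pqueries) {
  keys <- vapply(pqueries, function(pq) {
    paste(paste(sort(pquery_names(pq)), collapse = "\r"),
          paste(vapply(pq$placements, function(r) {
            paste(vapply(r, function(v) paste(format(v, digits = 17),
                                              collapse = ","),
                         character(1)), collapse = "|")
          }, character(1)), collapse = ";"),
          sep = "\n")
  }, character(1))
  out <- list()
  seen <- character(0)
  for (i in seq_along(pqueries)) {
    k <- keys[i]
    j <- match(k, seen)
    if (is.na(j)) {
      seen <- c(seen, k)
      out[[length(out) + 1L]] <- pqueries[[i]]
    } else {
      a <- out[[j]]
      b <- pqueries[[i]]
      am <- if (is.null(a$multiplicities)) {
        data.frame(name = a$names, multiplicity = 1,
                   stringsAsFactors = FALSE)
      } else a$multiplicities
      bm <- if (is.null(b$multiplicities)) {
        data.frame(name = b$names, multiplicity = 1,
                   stringsAsFactors = FALSE)
      } else b$multiplicities
      comb <- stats::aggregate(multiplicity ~ name, rbind(am, bm), sum)
      out[[j]] <- pquery(a$placements, multiplicities = comb)
    }
  }
  out
}

#' Best placement of a pquery under a criterion
#'
#' Maximizes `like_weight_ratio`, `post_prob` or `likelihood`, or minimizes
#' `parsimony`. Ties are broken by the lowest edge number, then by first
#' occurrence in the pquery.
#'
#' @param pq A [pquery()].
#' @param fields The document's field vector.
#' @param criterion One of `"like_weight_ratio"`, `"post_prob"`,
#'   `"likelihood"`, `"parsimony"`.
#' @return The winning placement row (a list of values).
#' @export
best_placement <- function(pq, fields,
                           criterion = c("like_weight_ratio", "post_prob",
                                         "likelihood", "parsimony")) {
  stopifnot(inherits(pq, "jplace_pquery"))
  criterion <- match.arg(criterion)
  ci <- match(criterion, fields)
  if (is.na(ci)) {
    stop_jplace("criterion field '", criterion,
                "' is not among the fields [",
                paste(fields, collapse = ", "), "]",
                class = "jplace_usage_error")
  }
  scores <- vapply(pq$placements, function(row) {
    v <- row[[ci]]
    if (is.numeric(v)) v else NA_real_
  }, double(1))
  if (criterion == "parsimony") scores <- -scores
  edges <- vapply(pq$placements, row_edge, integer(1), fields = fields)
  best <- which(scores == max(scores, na.rm = TRUE))
  best <- best[edges[best] == min(edges[best])]
  pq$placements[[best[1]]]
}

#' Total multiplicity of a pquery
#'
#' The number of names when the pquery carries a name list, or the sum of
#' the multiplicities when it carries named multiplicities.
#'
#' @param pq A [pquery()].
#' @return A positive number.
#' @export
total_multiplicity <- function(pq) {
  stopifnot(inherits(pq, "jplace_pquery"))
  if (!is.null(pq$names)) length(pq$names) else sum(pq$multiplicities$multiplicity)
}

#' Convert a name list to named multiplicities
#'
#' Each name receives multiplicity `transform(1)`; the default identity
#' gives every name multiplicity 1, conserving [total_multiplicity()].
#' A pquery already carrying multiplicities is refused, so a transform can
#' never be applied twice silently.
#'
#' @param pq A [pquery()] with a name list.
#' @param transform A function real -> real applied to the unit count.
#' @return A new `jplace_pquery` with named multiplicities.
#' @export
names_to_multiplicities <- function(pq, transform = identity) {
  stopifnot(inherits(pq, "jplace_pquery"))
  if (is.null(pq$names)) {
    stop_jplace("pquery already carries named multiplicities",
                class = "jplace_usage_error")
  }
  pquery(pq$placements, multiplicities = data.frame(
    name = pq$names,
    multiplicity = vapply(pq$names, function(n) as.double(transform(1)),
                          double(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  ))
}

#' Relational (two-table) export of a document
#'
#' Assigns a dense 0-based `placement_id` to every placement row in document
#' order and returns two tables: a placement table with one column per field,
#' and a name table mapping every `placement_id` to each of its pquery's
#' names (or named multiplicities) — the full cross product of a pquery's
#' names and placements. Names originating from a plain name list get
#' multiplicity 1.
#'
#' @param doc A [jplace_document()].
#' @return A list with `data.frame` components `placements` (columns
#'   `placement_id` + one per field) and `names` (columns `placement_id`,
#'   `name`, `multiplicity`).
#' @export
to_tables <- function(doc) {
  stopifnot(inherits(doc, "jplace"))
  nf <- length(doc$fields)
  all_rows <- list()
  name_rows <- list()
  pid <- 0L
  for (pq in doc$pqueries) {
    ids <- pid + seq_along(pq$placements) - 1L
    all_rows <- c(all_rows, pq$placements)
    nm <- if (!is.null(pq$names)) {
      data.frame(name = pq$names, multiplicity = 1,
                 stringsAsFactors = FALSE)
    } else {
      pq$multiplicities
    }
    for (id in ids) {
      name_rows[[length(name_rows) + 1L]] <-
        data.frame(placement_id = id, name = nm$name,
                   multiplicity = nm$multiplicity,
                   stringsAsFactors = FALSE)
    }
    pid <- pid + length(pq$placements)
  }

  cols <- lapply(seq_len(nf), function(i) {
    vals <- lapply(all_rows, function(r) if (i <= length(r)) r[[i]] else NA)
    scalar_num <- all(vapply(vals, function(v) is.numeric(v) &&
                               length(v) == 1L, logical(1)))
    scalar_chr <- all(vapply(vals, function(v) is.character(v) &&
                               length(v) == 1L, logical(1)))
    if (length(vals) == 0L) {
      if (doc$fields[i] %in% c(.integer_fields, .float_fields)) {
        numeric(0)
      } else {
        character(0)
      }
    } else if (scalar_num) {
      unlist(vals)
    } else if (scalar_chr) {
      unlist(vals)
    } else {
      I(vals)
    }
  })
  names(cols) <- doc$fields
  placements <- do.call(
    data.frame,
    c(list(placement_id = seq_along(all_rows) - 1L), cols,
      list(stringsAsFactors = FALSE, check.names = FALSE))
  )
  names_tab <- if (length(name_rows) == 0L) {
    data.frame(placement_id = integer(0), name = character(0),
               multiplicity = double(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, name_rows)
  }
  rownames(names_tab) <- NULL
  list(placements = placements, names = names_tab)
}

#' Graft best placements onto the reference tree as pendant branches
#'
#' Renders one pendant branch per pquery: the best placement (under
#' `criterion`) is materialized by splitting its edge at `distal_length`
#' from the distal (child-side) node and attaching a new leaf on a pendant
#' edge of length `pendant_length`. The leaf is labeled by the pquery's
#' first name, or all names joined by `sep` when `name_policy = "join"`.
#' Edge numbers and comments are dropped from the output; reference branch
#' lengths are conserved, so the grafted tree's total length equals the
#' reference total plus the sum of pendant lengths.
#'
#' A `distal_length` exceeding its edge's branch length is clamped to the
#' branch length with a warning, or rejected when `strict = TRUE`.
#'
#' @param doc A [jplace_document()] whose fields include `distal_length`
#'   and `pendant_length`, on a tree with branch lengths.
#' @param criterion Passed to [best_placement()]; defaults to the first of
#'   `like_weight_ratio`, `post_prob`, `parsimony` present in the fields.
#' @param name_policy `"first"` or `"join"`.
#' @param sep Separator for `name_policy = "join"`.
#' @param strict Error (instead of clamp + warn) on an out-of-range
#'   `distal_length`.
#' @return An [edge_tree()] without edge numbers.
#' @export
graft_jplace <- function(doc, criterion = NULL,
                         name_policy = c("first", "join"), sep = ",",
                         strict = FALSE) {
  stopifnot(inherits(doc, "jplace"))
  name_policy <- match.arg(name_policy)
  for (f in c("distal_length", "pendant_length")) {
    if (!f %in% doc$fields) {
      stop_jplace("grafting requires field '", f, "'",
                  class = "jplace_usage_error")
    }
  }
  if (is.null(criterion)) {
    criterion <- intersect(c("like_weight_ratio", "post_prob", "parsimony"),
                           doc$fields)[1]
    if (is.na(criterion)) {
      stop_jplace("no usable criterion field present ",
                  "(like_weight_ratio, post_prob or parsimony)",
                  class = "jplace_usage_error")
    }
  }

  # one insertion per pquery, grouped by target edge
  inserts <- list()
  for (pq in doc$pqueries) {
    row <- best_placement(pq, doc$fields, criterion)
    en <- row_edge(row, doc$fields)
    node <- edge_lookup(doc$tree, en)  # errors on unknown edge
    len <- node$branch_length
    if (is.null(len)) {
      if (strict) {
        stop_jplace("edge {", en, "} has no branch length; cannot graft",
                    class = "jplace_usage_error")
      }
      warning("edge {", en, "} has no branch length; attaching at its node",
              call. = FALSE)
      len <- 0
    }
    distal <- placement_value(row, doc$fields, "distal_length")
    pendant <- placement_value(row, doc$fields, "pendant_length")
    if (distal > len) {
      if (strict) {
        stop_jplace("distal_length ", fmt_number(distal),
                    " exceeds branch length ", fmt_number(len),
                    " of edge {", en, "}",
                    class = "jplace_usage_error")
      }
      warning("distal_length ", fmt_number(distal),
              " clamped to branch length ", fmt_number(len),
              " of edge {", en, "}", call. = FALSE)
      distal <- len
    }
    nms <- pquery_names(pq)
    label <- if (name_policy == "first") nms[1] else paste(nms,
                                                           collapse = sep)
    key <- as.character(en)
    inserts[[key]] <- c(inserts[[key]],
                        list(list(distal = distal, pendant = pendant,
                                  label = label)))
  }

  # Rebuild the tree; where an edge has insertions, split it into segments
  # (distal end upward) and hang one pendant leaf at each split point.
  rebuild <- function(node) {
    kids <- lapply(node$children, rebuild)
    clean <- tree_node(label = node$label, children = kids,
                       branch_length = node$branch_length)
    key <- if (is.null(node$edge_number)) NULL else
      as.character(node$edge_number)
    ins <- if (is.null(key)) NULL else inserts[[key]]
    if (is.null(ins)) return(clean)
    ord <- order(vapply(ins, function(x) x$distal, double(1)))
    ins <- ins[ord]
    d <- vapply(ins, function(x) x$distal, double(1))
    had_length <- !is.null(node$branch_length)
    L <- if (had_length) node$branch_length else 0
    current <- clean
    current$branch_length <- d[1]
    for (i in seq_along(ins)) {
      pend <- tree_node(label = ins[[i]]$label,
                        branch_length = ins[[i]]$pendant)
      seg <- if (i < length(ins)) d[i + 1] - d[i] else L - d[i]
      current <- tree_node(children = list(current, pend),
                           branch_length = seg)
    }
    if (!had_length) current$branch_length <- NULL
    current
  }
  edge_tree(rebuild(doc$tree$root))
}

#' Canonically renumber a document's tree and remap its placements
#'
#' Rewrites the reference tree with [canonical_edge_numbering()] and remaps
#' every placement's `edge_num` through the old-number -> same-edge -> new-
#' number correspondence, so placements stay on the same physical edges.
#' Idempotent on documents whose trees already follow the convention.
#'
#' @param doc A [jplace_document()].
#' @return A new `jplace` document.
#' @export
renumber_jplace <- function(doc) {
  stopifnot(inherits(doc, "jplace"))
  newtree <- canonical_edge_numbering(doc$tree)
  map <- new.env(parent = emptyenv())
  walk2 <- function(a, b) {
    if (!is.null(a$edge_number)) {
      assign(as.character(a$edge_number), b$edge_number, envir = map)
    }
    for (i in seq_along(a$children)) walk2(a$children[[i]], b$children[[i]])
  }
  walk2(doc$tree$root, newtree$root)
  ei <- match("edge_num", doc$fields)
  doc$pqueries <- lapply(doc$pqueries, function(pq) {
    pq$placements <- lapply(pq$placements, function(row) {
      old <- as.character(as.integer(row[[ei]]))
      new <- get0(old, envir = map)
      if (is.null(new)) {
        stop_jplace("placement on edge {", old,
                    "} which is not numbered in the tree",
                    class = "jplace_validation_error")
      }
      row[[ei]] <- as.double(new)
      row
    })
    pq
  })
  doc$tree <- newtree
  doc
}
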
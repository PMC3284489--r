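# Edge-numbered Newick dialect: standard Newick extended with {N} edge
# numbers and [comment] edge annotations, as used by jplace reference trees.

#' Construct a tree node
#'
#' Nodes are plain recursive lists. Child order is significant throughout the
#' package (planar identity): two trees that differ only in the order of
#' children are different trees.
#'
#' @param label Node label (taxon name or internal label), or `NULL`.
#' @param children List of child nodes, in left-to-right written order.
#' @param branch_length Length of the edge above this node, or `NULL`.
#' @param edge_comment Verbatim content of a `[...]` annotation, or `NULL`.
#' @param edge_number Integer edge number from `{N}`, or `NULL`.
#' @return A list of class `jplace_node`.
#' @export
tree_node <- function(label = NULL, children = list(), branch_length = NULL,
                      edge_comment = NULL, edge_number = NULL) {
  if (!is.null(branch_length)) branch_length <- as.double(branch_length)
  if (!is.null(edge_number)) edge_number <- as.integer(edge_number)
  if (!is.null(label)) label <- as.character(label)
  if (!is.null(edge_comment)) edge_comment <- as.character(edge_comment)
  structure(
    list(label = label, children = children, branch_length = branch_length,
         edge_comment = edge_comment, edge_number = edge_number),
    class = "jplace_node"
  )
}

#' Construct an edge tree
#'
#' An `edge_tree` wraps a root [tree_node()] together with an index from edge
#' number to the node *below* that edge (the node the edge leads to). The
#' top-level node may itself carry an edge number. The index is derived from
#' the node-stored numbers and rebuilt here, so it is always consistent.
#'
#' @param root A `jplace_node`.
#' @return An object of class `edge_tree`.
#' @export
edge_tree <- function(root) {
  stopifnot(inherits(root, "jplace_node"))
  index <- list()
  walk <- function(node, path) {
    if (!is.null(node$edge_number)) {
      key <- as.character(node$edge_number)
      if (!is.null(index[[key]])) {
        stop_jplace("duplicate edge number {", key, "} in tree",
                    class = "jplace_validation_error")
      }
      index[[key]] <<- path
    }
    for (i in seq_along(node$children)) {
      walk(node$children[[i]], c(path, i))
    }
  }
  walk(root, integer(0))
  structure(list(root = root, index = index), class = "edge_tree")
}

stop_jplace <- function(..., class, call. = FALSE) {
  stop(structure(
    class = c(class, "jplace_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

#' @export
print.edge_tree <- function(x, ...) {
  cat("edge_tree:", n_leaves(x$root), "leaves,",
      length(x$index), "numbered edges\n")
  cat(write_newick_edges(x), "\n")
  invisible(x)
}

n_leaves <- function(node) {
  if (length(node$children) == 0L) return(1L)
  sum(vapply(node$children, n_leaves, integer(1)))
}

#' Edge numbers present in a tree
#' @param tree An `edge_tree`.
#' @return Sorted integer vector of edge numbers.
#' @export
edge_numbers <- function(tree) {
  stopifnot(inherits(tree, "edge_tree"))
  sort(as.integer(names(tree$index)))
}

# --- parser ------------------------------------------------------------------

# Characters that terminate an unquoted label.
.label_stop <- c("(", ")", ",", ";", ":", "[", "]", "{", "}",
                 " ", "\t", "\n", "\r")

#' Parse an edge-numbered Newick string
#'
#' Parses standard Newick extended with `{N}` edge numbers and `[...]` edge
#' comments. After a node, the `:length`, `[comment]` and `{number}` tokens
#' are accepted in any relative order (files in the wild print both
#' `A:.01[e]{0}` and `D:.01{3}[g]`); whitespace between tokens is ignored.
#' Comments are stored verbatim and never interpreted; nested brackets are
#' rejected. Plain Newick (no braces) parses with all edge numbers absent.
#'
#' @param text A single Newick statement terminated by `;`.
#' @param strict If `TRUE` (default) a negative branch length is an error;
#'   if `FALSE` it is only a warning.
#' @return An [edge_tree()].
#' @examples
#' tr <- parse_newick_edges("((A:0.2{0},B:0.09{1}):0.7{2},C:0.5{3}){4};")
#' edge_numbers(tr)
#' @export
parse_newick_edges <- function(text, strict = TRUE) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  env <- new.env(parent = emptyenv())
  env$pos <- 1L

  perr <- function(msg) {
    stop_jplace("newick parse error at character ", env$pos, ": ", msg,
                class = "jplace_parse_error")
  }
  peek <- function() if (env$pos <= n) chars[[env$pos]] else ""
  advance <- function() env$pos <- env$pos + 1L
  skip_ws <- function() {
    while (env$pos <= n && chars[[env$pos]] %in% c(" ", "\t", "\n", "\r")) {
      advance()
    }
  }

  read_label <- function() {
    start <- env$pos
    while (env$pos <= n && !(chars[[env$pos]] %in% .label_stop)) advance()
    if (env$pos == start) NULL else paste(chars[start:(env$pos - 1L)],
                                          collapse = "")
  }

  read_number_token <- function() {
    start <- env$pos
    ok <- c(as.character(0:9), ".", "-", "+", "e", "E")
    while (env$pos <= n && chars[[env$pos]] %in% ok) advance()
    if (env$pos == start) perr("expected a branch length after ':'")
    txt <- paste(chars[start:(env$pos - 1L)], collapse = "")
    val <- suppressWarnings(as.double(txt))
    if (is.na(val)) perr(paste0("invalid branch length '", txt, "'"))
    val
  }

  read_comment <- function() {
    # opening '[' already consumed
    start <- env$pos
    while (env$pos <= n && !(chars[[env$pos]] %in% c("]", "["))) advance()
    if (env$pos > n) perr("unbalanced '[': comment never closed")
    if (chars[[env$pos]] == "[") perr("nested '[' inside a comment")
    txt <- if (env$pos == start) "" else paste(chars[start:(env$pos - 1L)],
                                               collapse = "")
    advance()  # ']'
    txt
  }

  read_edge_number <- function() {
    # opening '{' already consumed
    start <- env$pos
    while (env$pos <= n && chars[[env$pos]] %in% as.character(0:9)) advance()
    if (env$pos > n) perr("unbalanced '{': edge number never closed")
    if (chars[[env$pos]] != "}") {
      perr(paste0("non-integer content in '{}' ('", chars[[env$pos]], "')"))
    }
    if (env$pos == start) perr("empty '{}' edge number")
    txt <- paste(chars[start:(env$pos - 1L)], collapse = "")
    advance()  # '}'
    as.integer(txt)
  }

  # label (optional) then :length, [comment], {number} in any order
  read_suffix <- function(node, allow_label = TRUE) {
    skip_ws()
    if (allow_label) {
      lab <- read_label()
      if (!is.null(lab)) node$label <- lab
    }
    seen <- c(length = FALSE, comment = FALSE, number = FALSE)
    repeat {
      skip_ws()
      ch <- peek()
      if (ch == ":") {
        if (seen[["length"]]) perr("duplicate ':' branch length")
        advance(); skip_ws()
        bl <- read_number_token()
        if (bl < 0) {
          if (strict) {
            stop_jplace("negative branch length ", bl,
                        class = "jplace_validation_error")
          }
          warning("negative branch length ", bl, call. = FALSE)
        }
        node$branch_length <- bl
        seen[["length"]] <- TRUE
      } else if (ch == "[") {
        if (seen[["comment"]]) perr("duplicate '[...]' comment")
        advance()
        node$edge_comment <- read_comment()
        seen[["comment"]] <- TRUE
      } else if (ch == "{") {
        if (seen[["number"]]) perr("duplicate '{...}' edge number")
        advance()
        node$edge_number <- read_edge_number()
        seen[["number"]] <- TRUE
      } else {
        break
      }
    }
    node
  }

  read_subtree <- function() {
    skip_ws()
    if (peek() == "(") {
      advance()
      children <- list()
      repeat {
        children[[length(children) + 1L]] <- read_subtree()
        skip_ws()
        ch <- peek()
        if (ch == ",") {
          advance()
        } else if (ch == ")") {
          advance()
          break
        } else if (ch == "") {
          perr("unbalanced '(': end of input inside a subtree")
        } else {
          perr(paste0("unexpected '", ch, "' inside a subtree"))
        }
      }
      node <- list(label = NULL, children = children, branch_length = NULL,
                   edge_comment = NULL, edge_number = NULL)
      read_suffix(node, allow_label = TRUE)
    } else if (peek() == ")") {
      perr("unbalanced ')'")
    } else {
      node <- list(label = NULL, children = list(), branch_length = NULL,
                   edge_comment = NULL, edge_number = NULL)
      read_suffix(node, allow_label = TRUE)
    }
  }

  root <- read_subtree()
  skip_ws()
  if (peek() != ";") perr("expected ';' at end of tree")
  advance()
  skip_ws()
  if (env$pos <= n) perr("trailing content after ';'")

  as_node <- function(x) {
    x$children <- lapply(x$children, as_node)
    do.call(tree_node, x)
  }
  edge_tree(as_node(root))
}

# --- writer ------------------------------------------------------------------

# Shortest decimal representation that round-trips through as.double().
fmt_number <- function(x) {
  if (is.null(x) || is.na(x)) return("null")
  if (is.infinite(x)) return(if (x > 0) "Infinity" else "-Infinity")
  for (d in 1:17) {
    s <- sprintf("%.*g", d, x)
    if (as.double(s) == x) return(s)
  }
  sprintf("%.17g", x)
}

#' Serialize an edge tree to the edge-numbered Newick dialect
#'
#' Tokens after each node are emitted in the fixed canonical order
#' `label:length{number}[comment]` with no internal whitespace, so that
#' `parse_newick_edges(write_newick_edges(t))` reproduces `t` exactly.
#'
#' @param tree An [edge_tree()].
#' @param include_branch_lengths Drop `:length` tokens when `FALSE`
#'   (the convention for parsimony reference trees).
#' @param include_comments Drop `[...]` tokens when `FALSE`.
#' @param include_edge_numbers Drop `{N}` tokens when `FALSE`
#'   (plain Newick output).
#' @return A single Newick string terminated by `;`.
#' @export
write_newick_edges <- function(tree, include_branch_lengths = TRUE,
                               include_comments = TRUE,
                               include_edge_numbers = TRUE) {
  stopifnot(inherits(tree, "edge_tree"))
  fmt <- function(node) {
    out <- ""
    if (length(node$children) > 0L) {
      out <- paste0("(",
                    paste(vapply(node$children, fmt, character(1)),
                          collapse = ","),
                    ")")
    }
    if (!is.null(node$label)) out <- paste0(out, node$label)
    if (include_branch_lengths && !is.null(node$branch_length)) {
      out <- paste0(out, ":", fmt_number(node$branch_length))
    }
    if (include_edge_numbers && !is.null(node$edge_number)) {
      out <- paste0(out, "{", node$edge_number, "}")
    }
    if (include_comments && !is.null(node$edge_comment)) {
      out <- paste0(out, "[", node$edge_comment, "]")
    }
    out
  }
  paste0(fmt(tree$root), ";")
}

# --- canonical numbering -----------------------------------------------------

#' Assign canonical post-order edge numbers
#'
#' Renumbers every edge 0..E-1 by a post-order traversal that descends left
#' (first-written) subtrees first; the top-level node receives the final
#' number. This is the convention placement programs are expected to follow,
#' making edge numbers comparable across tools. Any existing numbers are
#' discarded. The operation is idempotent and its output numbering is a
#' bijection onto 0..E-1.
#'
#' @param tree An [edge_tree()].
#' @return A new `edge_tree` with canonical numbers.
#' @export
canonical_edge_numbering <- function(tree) {
  stopifnot(inherits(tree, "edge_tree"))
  counter <- new.env(parent = emptyenv())
  counter$k <- 0L
  renumber <- function(node) {
    node$children <- lapply(node$children, renumber)
    node$edge_number <- counter$k
    counter$k <- counter$k + 1L
    node
  }
  edge_tree(renumber(tree$root))
}

#' Look up the node below a numbered edge
#'
#' @param tree An [edge_tree()].
#' @param edge_num Integer edge number.
#' @return The `jplace_node` below that edge.
#' @export
edge_lookup <- function(tree, edge_num) {
  stopifnot(inherits(tree, "edge_tree"))
  path <- tree$index[[as.character(as.integer(edge_num))]]
  if (is.null(path)) {
    stop_jplace("no edge numbered {", as.integer(edge_num), "} in tree",
                class = "jplace_lookup_error")
  }
  node <- tree$root
  for (i in path) node <- node$children[[i]]
  node
}

#' Test whether two edge trees are compatible for merging
#'
#' Compatible means identical as planar trees: same topology, same child
#' order, same labels and same edge numbers. Branch lengths are compared
#' within an absolute tolerance (default 0, i.e. exact equality of the
#' parsed values).
#'
#' @param a,b [edge_tree()] objects.
#' @param tolerance Absolute tolerance for branch-length comparison.
#' @return `TRUE` or `FALSE`.
#' @export
trees_compatible <- function(a, b, tolerance = 0) {
  stopifnot(inherits(a, "edge_tree"), inherits(b, "edge_tree"))
  same <- function(x, y) {
    if (!identical(x$label, y$label)) return(FALSE)
    if (!identical(x$edge_number, y$edge_number)) return(FALSE)
    if (is.null(x$branch_length) != is.null(y$branch_length)) return(FALSE)
    if (!is.null(x$branch_length) &&
        abs(x$branch_length - y$branch_length) > tolerance) return(FALSE)
    if (length(x$children) != length(y$children)) return(FALSE)
    for (i in seq_along(x$children)) {
      if (!same(x$children[[i]], y$children[[i]])) return(FALSE)
    }
    TRUE
  }
  same(a$root, b$root)
}

#' Total branch length of a tree
#'
#' Sum of all branch lengths present; nodes without a length contribute 0.
#'
#' @param tree An [edge_tree()].
#' @return Non-negative number.
#' @export
tree_total_length <- function(tree) {
  stopifnot(inherits(tree, "edge_tree"))
  total <- function(node) {
    bl <- if (is.null(node$branch_length)) 0 else node$branch_length
    bl + sum(vapply(node$children, total, double(1)))
  }
  total(tree$root)
}

#' Leaf labels in written (planar) order
#' @param tree An [edge_tree()].
#' @return Character vector (`NA` for unlabeled leaves).
#' @export
leaf_labels <- function(tree) {
  stopifnot(inherits(tree, "edge_tree"))
  labs <- function(node) {
    if (length(node$children) == 0L) {
      return(if (is.null(node$label)) NA_character_ else node$label)
    }
    unlist(lapply(node$children, labs))
  }
  labs(tree$root)
}
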
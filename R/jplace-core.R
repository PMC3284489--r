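# jplace document model: JSON parsing, semantic validation, serialization.

# Field symbols with defined semantics. Anything else is carried through
# untyped (the format is extensible).
.integer_fields <- c("edge_num", "parsimony")
.float_fields <- c("likelihood", "like_weight_ratio", "distal_length",
                   "pendant_length", "proximal_length", "marginal_prob",
                   "post_prob")
.known_fields <- c(.integer_fields, .float_fields)

#' Construct a pquery
#'
#' A pquery ("placed query") holds every candidate placement of one query
#' sequence, with exactly one of a name list (`names`) or a set of named
#' multiplicities (`multiplicities`). A named multiplicity is a
#' (name, positive real) pair standing for a possibly transformed count of
#' sequences.
#'
#' @param placements Nonempty list of placement rows; each row is a list of
#'   values aligned with the document's field order.
#' @param names Character vector of sequence names, or `NULL`.
#' @param multiplicities A `data.frame` with columns `name` (character) and
#'   `multiplicity` (positive numeric), or `NULL`.
#' @return An object of class `jplace_pquery`.
#' @export
pquery <- function(placements, names = NULL, multiplicities = NULL) {
  if (is.null(names) == is.null(multiplicities)) {
    stop_jplace("a pquery carries exactly one of 'names' or 'multiplicities'",
                class = "jplace_structure_error")
  }
  if (length(placements) == 0L) {
    stop_jplace("a pquery needs at least one placement",
                class = "jplace_structure_error")
  }
  if (!is.null(names)) {
    names <- as.character(names)
    if (length(names) == 0L) {
      stop_jplace("pquery name list is empty",
                  class = "jplace_structure_error")
    }
  }
  if (!is.null(multiplicities)) {
    stopifnot(is.data.frame(multiplicities),
              all(c("name", "multiplicity") %in% colnames(multiplicities)))
    multiplicities <- data.frame(
      name = as.character(multiplicities$name),
      multiplicity = as.double(multiplicities$multiplicity),
      stringsAsFactors = FALSE
    )
    if (nrow(multiplicities) == 0L) {
      stop_jplace("pquery multiplicity list is empty",
                  class = "jplace_structure_error")
    }
  }
  structure(list(placements = placements, names = names,
                 multiplicities = multiplicities),
            class = "jplace_pquery")
}

#' All names attached to a pquery
#' @param pq A [pquery()].
#' @return Character vector.
#' @export
pquery_names <- function(pq) {
  stopifnot(inherits(pq, "jplace_pquery"))
  if (!is.null(pq$names)) pq$names else pq$multiplicities$name
}

#' Construct a jplace document
#'
#' @param tree An [edge_tree()] (the reference tree).
#' @param fields Character vector of field names; must contain `"edge_num"`
#'   and be free of duplicates.
#' @param pqueries List of [pquery()] objects.
#' @param version Integer format version (canonically 3).
#' @param metadata Arbitrary named list (e.g. an `invocation` string), or
#'   `NULL`.
#' @param extra Named list of unrecognized top-level keys, preserved for
#'   round-tripping.
#' @return An object of class `jplace`.
#' @export
jplace_document <- function(tree, fields, pqueries = list(), version = 3L,
                            metadata = NULL, extra = list()) {
  stopifnot(inherits(tree, "edge_tree"))
  fields <- as.character(fields)
  if (anyDuplicated(fields)) {
    stop_jplace("duplicate field names: ",
                paste(unique(fields[duplicated(fields)]), collapse = ", "),
                class = "jplace_structure_error")
  }
  if (!"edge_num" %in% fields) {
    stop_jplace("'edge_num' must be among the fields",
                class = "jplace_structure_error")
  }
  if (length(extra) == 0L) extra <- list()
  structure(list(tree = tree, fields = fields, pqueries = pqueries,
                 version = as.integer(version), metadata = metadata,
                 extra = extra),
            class = "jplace")
}

#' @export
print.jplace <- function(x, ...) {
  cat("jplace document (version ", x$version, ")\n", sep = "")
  cat("  tree: ", n_leaves(x$tree$root), " leaves, ",
      length(x$tree$index), " numbered edges\n", sep = "")
  cat("  fields: ", paste(x$fields, collapse = ", "), "\n", sep = "")
  np <- sum(vapply(x$pqueries, function(pq) length(pq$placements),
                   integer(1)))
  cat("  pqueries: ", length(x$pqueries), " (", np, " placements)\n",
      sep = "")
  invisible(x)
}

#' Extract one named value from a placement row
#' @param row A placement row (list of values).
#' @param fields The document's field vector.
#' @param field Field name to extract.
#' @return The value, or `NULL` if the field is absent.
#' @export
placement_value <- function(row, fields, field) {
  i <- match(field, fields)
  if (is.na(i) || i > length(row)) return(NULL)
  row[[i]]
}

# --- text normalization ------------------------------------------------------

# Typeset copies of jplace documents often carry typographic quotes and a
# Unicode minus; normalize them to ASCII so such text is parseable JSON.
normalize_text <- function(text) {
  from <- c("“", "”", "‘", "’", "−", " ")
  to <- c("\"", "\"", "'", "'", "-", " ")
  for (i in seq_along(from)) {
    text <- gsub(from[i], to[i], text, fixed = TRUE)
  }
  text
}

# --- parsing -----------------------------------------------------------------

#' Parse a jplace document from JSON text
#'
#' Accepts the five top-level keys (`tree`, `fields`, `placements`,
#' `metadata`, `version`) in any order; `metadata` is optional, the rest are
#' required. Unknown top-level keys are preserved and written back out.
#'
#' @param text JSON text (a single object).
#' @param lenient_text Normalize typographic quotes and Unicode minus signs
#'   to ASCII before JSON parsing (useful for text copied out of typeset
#'   documents).
#' @return A [jplace_document()].
#' @export
parse_jplace <- function(text, lenient_text = FALSE) {
  stopifnot(is.character(text))
  text <- paste(text, collapse = "\n")
  if (lenient_text) text <- normalize_text(text)
  obj <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) {
      stop_jplace("not valid JSON: ", conditionMessage(e),
                  class = "jplace_parse_error")
    }
  )
  if (!is.list(obj) || is.null(names(obj))) {
    stop_jplace("a jplace file must contain a single JSON object",
                class = "jplace_structure_error")
  }
  for (key in c("tree", "fields", "placements", "version")) {
    if (!key %in% names(obj)) {
      stop_jplace("missing required top-level key '", key, "'",
                  class = "jplace_structure_error")
    }
  }

  fields <- vapply(obj$fields, function(f) {
    if (!is.character(f) || length(f) != 1L) {
      stop_jplace("'fields' must be an array of strings",
                  class = "jplace_structure_error")
    }
    f
  }, character(1))

  tree <- parse_newick_edges(obj$tree)

  pqueries <- lapply(seq_along(obj$placements), function(i) {
    parse_pquery(obj$placements[[i]], i, length(fields))
  })

  version <- obj$version
  if (!is.numeric(version) || length(version) != 1L ||
      version != as.integer(version)) {
    stop_jplace("'version' must be an integer",
                class = "jplace_structure_error")
  }

  extra <- obj[setdiff(names(obj), c("tree", "fields", "placements",
                                     "metadata", "version"))]
  jplace_document(tree = tree, fields = fields, pqueries = pqueries,
                  version = as.integer(version), metadata = obj$metadata,
                  extra = extra)
}

parse_pquery <- function(raw, i, n_fields) {
  where <- paste0("placements[", i, "]")
  if (!is.list(raw) || is.null(names(raw))) {
    stop_jplace(where, ": a pquery must be a JSON object",
                class = "jplace_structure_error")
  }
  if (!"p" %in% names(raw)) {
    stop_jplace(where, ": missing 'p' (placement list)",
                class = "jplace_structure_error")
  }
  has_n <- "n" %in% names(raw)
  has_nm <- "nm" %in% names(raw)
  if (has_n == has_nm) {
    stop_jplace(where, ": a pquery must have exactly one of 'n' or 'nm'",
                class = "jplace_structure_error")
  }
  rows <- lapply(seq_along(raw$p), function(j) {
    row <- raw$p[[j]]
    if (!is.list(row)) row <- as.list(row)
    if (length(row) != n_fields) {
      stop_jplace(where, ".p[", j, "]: row has ", length(row),
                  " values but there are ", n_fields, " fields",
                  class = "jplace_structure_error")
    }
    lapply(row, function(v) if (is.numeric(v)) as.double(v) else v)
  })
  if (length(rows) == 0L) {
    stop_jplace(where, ": placement list 'p' is empty",
                class = "jplace_structure_error")
  }
  if (has_n) {
    nm <- vapply(raw$n, function(x) {
      if (!is.character(x) || length(x) != 1L) {
        stop_jplace(where, ": 'n' must be an array of strings",
                    class = "jplace_structure_error")
      }
      x
    }, character(1))
    pquery(rows, names = nm)
  } else {
    pairs <- lapply(seq_along(raw$nm), function(j) {
      pr <- raw$nm[[j]]
      if (!is.list(pr) || length(pr) != 2L || !is.character(pr[[1]]) ||
          !is.numeric(pr[[2]])) {
        stop_jplace(where, ".nm[", j,
                    "]: expected a [name, multiplicity] pair",
                    class = "jplace_structure_error")
      }
      pr
    })
    pquery(rows, multiplicities = data.frame(
      name = vapply(pairs, function(p) p[[1]], character(1)),
      multiplicity = vapply(pairs, function(p) as.double(p[[2]]), double(1)),
      stringsAsFactors = FALSE
    ))
  }
}

#' Read a jplace document from a file
#' @param path Path to a `.jplace` file.
#' @inheritParams parse_jplace
#' @return A [jplace_document()].
#' @export
read_jplace <- function(path, lenient_text = FALSE) {
  parse_jplace(readLines(path, warn = FALSE, encoding = "UTF-8"),
               lenient_text = lenient_text)
}

# --- validation --------------------------------------------------------------

issue <- function(severity, path, message) {
  data.frame(severity = severity, path = path, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a jplace document
#'
#' Applies the format's semantic rules and returns every violation found as a
#' row of (severity, path, message); an empty result means a fully conformant
#' document. Errors: version not 3 (strict mode only), a placement on an edge
#' number absent from the tree, a row whose length disagrees with the field
#' count, a non-positive multiplicity, a non-integer parsimony score.
#' Warnings: `like_weight_ratio` or `post_prob` outside [0,1], a pquery's
#' `like_weight_ratio` summing above 1 (beyond a small rounding tolerance),
#' `distal_length` exceeding the branch length of its edge, a positive log
#' likelihood, and (lenient mode) a version other than 3.
#'
#' @param doc A [jplace_document()].
#' @param strict Treat a version other than 3 as an error rather than a
#'   warning.
#' @param lwr_tolerance Slack allowed on per-pquery `like_weight_ratio` sums
#'   before warning.
#' @return A `data.frame` with columns `severity`, `path`, `message`.
#' @export
validate_jplace <- function(doc, strict = FALSE, lwr_tolerance = 1e-6) {
  stopifnot(inherits(doc, "jplace"))
  issues <- list()
  add <- function(severity, path, message) {
    issues[[length(issues) + 1L]] <<- issue(severity, path, message)
  }

  if (doc$version != 3L) {
    add(if (strict) "ERROR" else "WARNING", "version",
        paste0("format version is ", doc$version, ", expected 3"))
  }
  if (!"edge_num" %in% doc$fields) {
    add("ERROR", "fields", "'edge_num' is missing from the fields")
  }
  if (anyDuplicated(doc$fields)) {
    add("ERROR", "fields", "duplicate field names")
  }

  known_edges <- as.integer(names(doc$tree$index))
  nf <- length(doc$fields)
  fi <- function(name) match(name, doc$fields)

  for (i in seq_along(doc$pqueries)) {
    pq <- doc$pqueries[[i]]
    base <- paste0("placements[", i, "]")
    if (!is.null(pq$multiplicities) &&
        any(pq$multiplicities$multiplicity <= 0)) {
      bad <- which(pq$multiplicities$multiplicity <= 0)
      add("ERROR", paste0(base, ".nm"),
          paste0("non-positive multiplicity for name(s) ",
                 paste(pq$multiplicities$name[bad], collapse = ", ")))
    }
    lwr_sum <- 0
    for (j in seq_along(pq$placements)) {
      row <- pq$placements[[j]]
      rpath <- paste0(base, ".p[", j, "]")
      if (length(row) != nf) {
        add("ERROR", rpath,
            paste0("row has ", length(row), " values but there are ",
                   nf, " fields"))
        next
      }
      num <- function(name) {
        v <- row[[fi(name)]]
        if (is.numeric(v)) v else NA_real_
      }
      if (!is.na(fi("edge_num"))) {
        en <- num("edge_num")
        if (is.na(en) || en != as.integer(en)) {
          add("ERROR", paste0(rpath, ".edge_num"),
              "edge_num must be an integer")
        } else if (!as.integer(en) %in% known_edges) {
          add("ERROR", paste0(rpath, ".edge_num"),
              paste0("edge number {", as.integer(en),
                     "} does not occur in the tree"))
        } else {
          node <- edge_lookup(doc$tree, as.integer(en))
          if (!is.na(fi("distal_length")) &&
              !is.null(node$branch_length)) {
            dl <- num("distal_length")
            if (!is.na(dl) && dl > node$branch_length) {
              add("WARNING", paste0(rpath, ".distal_length"),
                  paste0("distal_length ", fmt_number(dl),
                         " exceeds the branch length ",
                         fmt_number(node$branch_length), " of edge {",
                         as.integer(en), "}"))
            }
          }
        }
      }
      if (!is.na(fi("parsimony"))) {
        pv <- num("parsimony")
        if (is.na(pv) || pv != as.integer(pv)) {
          add("ERROR", paste0(rpath, ".parsimony"),
              "parsimony score must be an integer")
        }
      }
      if (!is.na(fi("likelihood"))) {
        ll <- num("likelihood")
        if (!is.na(ll) && ll > 0) {
          add("WARNING", paste0(rpath, ".likelihood"),
              paste0("log likelihood ", fmt_number(ll), " is positive"))
        }
      }
      for (probf in c("like_weight_ratio", "post_prob")) {
        if (!is.na(fi(probf))) {
          v <- num(probf)
          if (!is.na(v) && (v < 0 || v > 1)) {
            add("WARNING", paste0(rpath, ".", probf),
                paste0(probf, " ", fmt_number(v), " is outside [0, 1]"))
          }
        }
      }
      if (!is.na(fi("like_weight_ratio"))) {
        v <- num("like_weight_ratio")
        if (!is.na(v)) lwr_sum <- lwr_sum + v
      }
    }
    if (!is.na(fi("like_weight_ratio")) &&
        lwr_sum > 1 + lwr_tolerance) {
      add("WARNING", paste0(base, ".p"),
          paste0("like_weight_ratio values sum to ", fmt_number(lwr_sum),
                 " > 1"))
    }
  }

  if (length(issues) == 0L) {
    return(data.frame(severity = character(0), path = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

# --- serialization -----------------------------------------------------------

json_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  paste0("\"", s, "\"")
}

# A float keeps a decimal point ("1.0", never "1"); integers never get one.
fmt_json_number <- function(x, force_float = FALSE) {
  s <- fmt_number(x)
  if (force_float && !grepl("[.eE]", s)) s <- paste0(s, ".0")
  s
}

# Generic JSON value emitter (metadata, unknown fields, extra keys).
emit_json_value <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    if (!is.null(names(x)) && all(nzchar(names(x)))) {
      body <- vapply(seq_along(x), function(i) {
        paste0(json_escape(names(x)[i]), ": ", emit_json_value(x[[i]]))
      }, character(1))
      return(paste0("{", paste(body, collapse = ", "), "}"))
    }
    body <- vapply(x, emit_json_value, character(1))
    return(paste0("[", paste(body, collapse = ", "), "]"))
  }
  if (length(x) != 1L) {
    return(paste0("[", paste(vapply(x, emit_json_value, character(1)),
                             collapse = ", "), "]"))
  }
  if (is.character(x)) return(json_escape(x))
  if (is.logical(x)) return(if (x) "true" else "false")
  if (is.numeric(x)) return(fmt_json_number(x))
  stop_jplace("cannot serialize metadata value of class ",
              paste(class(x), collapse = "/"),
              class = "jplace_write_error")
}

emit_row <- function(row, fields) {
  vals <- vapply(seq_along(row), function(i) {
    v <- row[[i]]
    f <- if (i <= length(fields)) fields[i] else ""
    if (is.numeric(v)) {
      if (f %in% .integer_fields) {
        fmt_json_number(v)
      } else if (f %in% .float_fields) {
        fmt_json_number(v, force_float = TRUE)
      } else {
        fmt_json_number(v)
      }
    } else {
      emit_json_value(v)
    }
  }, character(1))
  paste0("[", paste(vals, collapse = ", "), "]")
}

#' Serialize a jplace document to JSON text
#'
#' Emits strict ASCII JSON with the top-level keys in the fixed order
#' `tree`, `placements`, `metadata`, `version`, `fields` (then any preserved
#' unknown keys). Numbers use the shortest representation that round-trips;
#' values of real-valued fields always keep a decimal point.
#' `parse_jplace(write_jplace(d))` reproduces `d`.
#'
#' @param doc A [jplace_document()].
#' @param indent `NULL` for compact one-line output, or a number of spaces
#'   for a pretty-printed layout.
#' @return A single JSON string.
#' @export
write_jplace <- function(doc, indent = NULL) {
  stopifnot(inherits(doc, "jplace"))
  nl <- if (is.null(indent)) "" else "\n"
  pad <- function(depth) {
    if (is.null(indent)) "" else strrep(" ", indent * depth)
  }

  emit_pquery <- function(pq, depth) {
    rows <- vapply(pq$placements, emit_row, character(1),
                   fields = doc$fields)
    p_body <- paste0("[", paste(rows, collapse = ", "), "]")
    if (!is.null(pq$names)) {
      tag <- paste0("\"n\": [",
                    paste(vapply(pq$names, json_escape, character(1)),
                          collapse = ", "), "]")
    } else {
      prs <- vapply(seq_len(nrow(pq$multiplicities)), function(i) {
        paste0("[", json_escape(pq$multiplicities$name[i]), ", ",
               fmt_json_number(pq$multiplicities$multiplicity[i]), "]")
      }, character(1))
      tag <- paste0("\"nm\": [", paste(prs, collapse = ", "), "]")
    }
    paste0(pad(depth), "{\"p\": ", p_body, ", ", tag, "}")
  }

  parts <- character(0)
  parts <- c(parts, paste0(pad(1), "\"tree\": ",
                           json_escape(write_newick_edges(doc$tree))))
  if (length(doc$pqueries) == 0L) {
    parts <- c(parts, paste0(pad(1), "\"placements\": []"))
  } else {
    pq_txt <- vapply(doc$pqueries, emit_pquery, character(1), depth = 2)
    parts <- c(parts, paste0(pad(1), "\"placements\": [", nl,
                             paste(pq_txt, collapse = paste0(",", nl)),
                             nl, pad(1), "]"))
  }
  if (!is.null(doc$metadata)) {
    parts <- c(parts, paste0(pad(1), "\"metadata\": ",
                             emit_json_value(doc$metadata)))
  }
  parts <- c(parts, paste0(pad(1), "\"version\": ", doc$version))
  parts <- c(parts, paste0(
    pad(1), "\"fields\": [",
    paste(vapply(doc$fields, json_escape, character(1)), collapse = ", "),
    "]"))
  for (key in names(doc$extra)) {
    parts <- c(parts, paste0(pad(1), json_escape(key), ": ",
                             emit_json_value(doc$extra[[key]])))
  }
  paste0("{", nl, paste(parts, collapse = paste0(",", nl)), nl, "}")
}

#' Write a jplace document to a file
#' @param doc A [jplace_document()].
#' @param path Output path.
#' @param indent Passed to [write_jplace()]; defaults to pretty-printing.
#' @return `path`, invisibly.
#' @export
save_jplace <- function(doc, path, indent = 1L) {
  writeLines(write_jplace(doc, indent = indent), path, useBytes = TRUE)
  invisible(path)
}
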
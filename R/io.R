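#' Read a protein-protein interaction network from an edge list
#'
#' Parses a two-column, tab- or whitespace-separated edge list into a simple
#' undirected [igraph][igraph::igraph-package] graph. Protein identifiers are
#' opaque, case-sensitive strings. Lines starting with `#` and blank lines are
#' skipped. Self-loops and duplicate edges are silently dropped (a message
#' reports how many); extra columns beyond the first two are ignored when
#' `allow_extra_columns = TRUE`.
#'
#' @param source path to a file, or a connection, or a character vector of
#'   lines (useful for tests).
#' @param allow_extra_columns if `FALSE`, a line with more than two tokens is
#'   a parse error.
#' @return an undirected, simple `igraph` graph with a `name` vertex attribute.
#' @export
read_edge_list <- function(source, allow_extra_columns = TRUE) {
  lines <- read_text_lines(source)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  toks <- strsplit(trimws(lines[idx]), "[ \t]+")
  nt <- lengths(toks)
  if (any(nt < 2L)) {
    stop("malformed edge list: fewer than 2 tokens on line ",
         idx[which(nt < 2L)[1L]], call. = FALSE)
  }
  if (!allow_extra_columns && any(nt > 2L)) {
    stop("malformed edge list: more than 2 tokens on line ",
         idx[which(nt > 2L)[1L]], call. = FALSE)
  }
  u <- vapply(toks, `[`, "", 1L)
  v <- vapply(toks, `[`, "", 2L)
  self <- u == v
  a <- pmin(u[!self], v[!self])
  b <- pmax(u[!self], v[!self])
  dup <- duplicated(paste(a, b, sep = "\r"))
  n_dropped <- sum(self) + sum(dup)
  if (n_dropped > 0L) {
    message("read_edge_list: dropped ", sum(self), " self-loop(s) and ",
            sum(dup), " duplicate edge(s)")
  }
  verts <- unique(c(u, v))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[!dup], to = b[!dup], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE)
  )
  g
}

#' Write a network as a canonical edge list
#'
#' One edge per line, endpoints tab-separated in lexicographic order, lines
#' sorted; reading the result back reproduces the edge set exactly (isolated
#' vertices are not representable in an edge list and are lost on round trip).
#'
#' @param net an `igraph` graph with named vertices.
#' @param sink file path or connection.
#' @export
write_edge_list <- function(net, sink) {
  el <- edge_name_matrix(net)
  if (nrow(el) == 0L) {
    writeLines(character(0), sink)
    return(invisible(NULL))
  }
  a <- pmin(el[, 1L], el[, 2L])
  b <- pmax(el[, 1L], el[, 2L])
  lines <- sort(paste(a, b, sep = "\t"))
  writeLines(lines, sink)
  invisible(NULL)
}

#' Read a complex catalog
#'
#' One complex per line, members whitespace-separated. With `named = TRUE` the
#' first (tab-delimited) token is the complex name. Duplicate members within a
#' line are collapsed with a warning. Lines starting with `#` are comments.
#'
#' @param source path, connection or character vector of lines.
#' @param named whether the first token of each line is a complex name.
#' @return a `complex_catalog`: a list of character vectors of member
#'   identifiers, in file order, named when `named = TRUE`.
#' @export
read_complex_catalog <- function(source, named = FALSE) {
  lines <- read_text_lines(source)
  idx <- which(!grepl("^\\s*(#|$)", lines))
  out <- vector("list", length(idx))
  nms <- character(length(idx))
  warned <- FALSE
  for (i in seq_along(idx)) {
    ln <- trimws(lines[idx[i]])
    if (named) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(parts) < 2L) {
        # fall back: first whitespace token is the name
        parts <- sub("[ \t]+", "\t", ln)
        parts <- strsplit(parts, "\t", fixed = TRUE)[[1L]]
      }
      if (length(parts) < 2L) {
        stop("complex catalog line ", idx[i], " has a name but no members",
             call. = FALSE)
      }
      nms[i] <- parts[1L]
      members <- strsplit(trimws(paste(parts[-1L], collapse = " ")),
                          "[ \t]+")[[1L]]
    } else {
      members <- strsplit(ln, "[ \t]+")[[1L]]
    }
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      stop("complex catalog line ", idx[i], " has an empty member set",
           call. = FALSE)
    }
    if (anyDuplicated(members)) {
      warned <- TRUE
      members <- unique(members)
    }
    out[[i]] <- members
  }
  if (warned) {
    warning("duplicate members within a complex were collapsed",
            call. = FALSE)
  }
  if (named) names(out) <- nms
  as_complex_catalog(out)
}

#' Write a complex catalog
#'
#' @param catalog a `complex_catalog` (or plain list of character vectors).
#' @param sink file path or connection.
#' @param named write the list names as a leading tab-delimited token.
#' @export
write_complex_catalog <- function(catalog, sink, named = !is.null(names(catalog))) {
  lines <- vapply(seq_along(catalog), function(i) {
    body <- paste(catalog[[i]], collapse = " ")
    if (named) paste(names(catalog)[i], body, sep = "\t") else body
  }, "")
  writeLines(lines, sink)
  invisible(NULL)
}

#' Coerce to a complex catalog
#'
#' @param x a list of character vectors (each a complex's member set).
#' @return `x` with class `complex_catalog`.
#' @export
as_complex_catalog <- function(x) {
  stopifnot(is.list(x))
  structure(x, class = "complex_catalog")
}

#' @export
print.complex_catalog <- function(x, ...) {
  sizes <- lengths(x)
  cat("Complex catalog:", length(x), "complexes,",
      length(unique(unlist(x))), "distinct proteins\n")
  if (length(x)) {
    cat("  sizes: min", min(sizes), "/ median", stats::median(sizes),
        "/ max", max(sizes), "\n")
  }
  invisible(x)
}

#' Read functional annotation groups (GMT format)
#'
#' Standard GMT: `name TAB description TAB member TAB member ...`. Duplicate
#' group names keep the last occurrence with a warning.
#'
#' @param source path, connection or character vector of lines.
#' @return a named list of member character vectors, with a `description`
#'   attribute (named character vector) carrying the second GMT field.
#' @export
read_annotation_groups <- function(source) {
  lines <- read_text_lines(source)
  idx <- which(!grepl("^\\s*(#|$)", lines))
  if (length(idx) == 0L) {
    return(structure(list(), description = character(0)))
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    stop("malformed GMT line ", idx[which(bad)[1L]],
         ": fewer than 3 tab-separated fields", call. = FALSE)
  }
  nms <- vapply(parts, `[`, "", 1L)
  desc <- vapply(parts, `[`, "", 2L)
  groups <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  if (anyDuplicated(nms)) {
    warning("duplicate group names in GMT input; keeping the last occurrence",
            call. = FALSE)
    keep <- !duplicated(nms, fromLast = TRUE)
    nms <- nms[keep]; desc <- desc[keep]; groups <- groups[keep]
  }
  names(groups) <- nms
  names(desc) <- nms
  structure(groups, description = desc)
}

#' Write an edge score table
#'
#' TSV with a commented header line naming the score variant, then columns
#' `u`, `v`, `score`.
#'
#' @param scores an `edge_scores` table from [score_all_edges()].
#' @param sink file path or connection.
#' @export
write_edge_scores <- function(scores, sink) {
  con <- if (is.character(sink)) {
    con <- file(sink, "w"); on.exit(close(con)); con
  } else sink
  writeLines(paste0("# variant=", attr(scores, "variant")), con)
  writeLines("u\tv\tscore", con)
  if (nrow(scores)) {
    writeLines(paste(scores$u, scores$v,
                     format(scores$score, digits = 10, trim = TRUE),
                     sep = "\t"), con)
  }
  invisible(NULL)
}

# -- internal helpers ---------------------------------------------------------

read_text_lines <- function(source) {
  if (is.character(source) && length(source) == 1L && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (inherits(source, "connection")) {
    readLines(source, warn = FALSE)
  } else if (is.character(source)) {
    source
  } else {
    stop("unsupported input source", call. = FALSE)
  }
}

# edge list of an igraph graph as a 2-column character matrix of vertex names
edge_name_matrix <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  if (!is.character(el)) mode(el) <- "character"
  el
}

# canonical "a|b" keys for undirected edges given by name vectors
edge_keys <- function(u, v) paste(pmin(u, v), pmax(u, v), sep = "|")
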
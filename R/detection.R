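#' Build the reliable virtual network
#'
#' Thresholds a pairwise similarity matrix at `tau`: the virtual network keeps
#' the full vertex set of the source network and connects `u != v` exactly
#' when `S(u,v) >= tau`. With `tau = 0` every pair is connected (all
#' similarities are nonnegative); raising `tau` can only remove edges. The
#' virtual network is a denoised, reliability-weighted rewiring of the
#' original: vertex pairs joined by many strong short walks become (or stay)
#' adjacent, pairs joined only through weak ties are disconnected.
#'
#' @param net the source `igraph` graph (provides the vertex set).
#' @param sim a `walk_similarity` object indexed by `net`'s vertices.
#' @param tau nonnegative similarity threshold.
#' @return an `igraph` graph with attributes `tau`, `beta`, `variant`
#'   recorded as graph attributes.
#' @export
build_virtual_network <- function(net, sim, tau) {
  stopifnot(tau >= 0)
  verts <- igraph::V(net)$name
  if (!identical(sort(verts), sort(rownames(sim$mat)))) {
    stop("similarity matrix is not indexed by the network's vertex set",
         call. = FALSE)
  }
  n <- length(verts)
  if (tau <= 0) {
    g <- igraph::make_full_graph(n, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = verts)
  } else {
    tm <- methods::as(methods::as(Matrix::triu(sim$mat, k = 1L), "CsparseMatrix"),
                      "TsparseMatrix")
    keep <- tm@x >= tau
    rn <- rownames(sim$mat)
    g <- igraph::graph_from_data_frame(
      data.frame(from = rn[tm@i[keep] + 1L], to = rn[tm@j[keep] + 1L],
                 stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = verts, stringsAsFactors = FALSE))
  }
  g <- igraph::set_graph_attr(g, "tau", tau)
  g <- igraph::set_graph_attr(g, "beta", sim$beta)
  g
}

#' Mine complex cores from a virtual network
#'
#' Cores are the inclusion-maximal cliques of the virtual network with at
#' least `min_core` members, in canonical order. Exact enumeration is used;
#' any maximal-clique finder would do, but exactness gives a testable
#' contract.
#'
#' @param vnet a virtual network from [build_virtual_network()].
#' @param min_core smallest admissible core size (`>= 2`).
#' @return a list of character vectors.
#' @export
mine_cores <- function(vnet, min_core = 3L) {
  stopifnot(min_core >= 2L)
  enumerate_maximal_cliques(vnet, min_size = min_core)
}

#' Average closeness of a vertex to a core
#'
#' `cl(v, U) = sum_{u in U} S(v, u) / (|U| + 1)`: the mean walk-similarity of
#' `v` to the core members (with the `|U| + 1` denominator as defined by the
#' method). Large values mean many strong short walks connect `v` to the
#' core.
#'
#' @param v a vertex identifier outside `core`.
#' @param core character vector of core members.
#' @param sim a `walk_similarity` object.
#' @return a nonnegative real.
#' @export
closeness_to_core <- function(v, core, sim) {
  stopifnot(!(v %in% core), length(core) >= 1L)
  sum(similarity_entries(sim, rep(v, length(core)), core)) / (length(core) + 1)
}

#' Select the attachments of a core
#'
#' Candidates are the vertices outside the core with at least one
#' original-network edge into it. A candidate `v` is selected when its
#' closeness `cl(v, U)` is at least the average closeness level
#' `acl = sum_{w in CS(U)} cl(w, U) / (|CS(U)| + |U|)`.
#'
#' @param net the original `igraph` graph.
#' @param core character vector of core members.
#' @param sim a `walk_similarity` object.
#' @return a character vector of attachment identifiers (possibly empty).
#' @export
select_attachments <- function(net, core, sim) {
  stopifnot(length(core) >= 1L)
  nbrs <- unique(unlist(lapply(core, function(u)
    igraph::neighbors(net, u)$name)))
  cand <- sort(setdiff(nbrs, core))
  if (length(cand) == 0L) return(character(0))
  cl <- vapply(cand, closeness_to_core, 0, core = core, sim = sim)
  acl <- sum(cl) / (length(cand) + length(core))
  cand[cl >= acl]
}

#' Detect protein complexes by the weak-ties core-attachment method
#'
#' The full pipeline: (1) compute the bridgeness of every interaction;
#' (2) weight edges by `exp(-B)` and form the truncated walk-polynomial
#' similarity matrix; (3) threshold it at `tau` into the virtual network;
#' (4) mine cores as maximal cliques of the virtual network; (5) recruit
#' attachments around each core by the average-closeness rule. Each core
#' yields one predicted complex (core plus attachments); predictions with
#' identical member sets are deduplicated (first kept) and the catalog is
#' canonically ordered. The procedure is fully deterministic.
#'
#' `tau` controls the size and number of cores (larger `tau`, sparser virtual
#' network, smaller cores) and has no universal default; sweeping it with
#' [sweep_parameter()] is recommended. `beta < 1` favours short walks.
#'
#' @param net an `igraph` graph with named vertices.
#' @param beta walk-discount parameter (default 0.618).
#' @param tau virtual-network similarity threshold (default 0.02).
#' @param variant bridgeness variant: `"weakties"` (default) or
#'   `"reference"`.
#' @param min_core smallest admissible core size.
#' @param max_neighborhood guard for the exact clique search.
#' @return a `complex_detection` object: a list with `complexes` (each a list
#'   with `core`, `attachments`, `members`), `params`, `n_vertices`,
#'   `n_edges`, `virtual_edges`, and the matched `call`. Use
#'   [as_complex_catalog()] / `as.list` semantics via `$complexes`, or
#'   [predicted_catalog()] for the plain member-set catalog.
#' @seealso [predicted_catalog()], [complex_stats()], [evaluate_complexes()]
#' @export
detect_complexes <- function(net, beta = 0.618, tau = 0.02,
                             variant = c("weakties", "reference"),
                             min_core = 3L, max_neighborhood = 200L) {
  variant <- match.arg(variant)
  stopifnot(tau >= 0, beta > 0, min_core >= 2L)
  cl <- match.call()
  if (igraph::ecount(net) == 0L) {
    return(new_complex_detection(list(), net, 0L, beta, tau, variant,
                                 min_core, cl))
  }
  sim <- pairwise_similarity(net, beta = beta, variant = variant,
                             max_neighborhood = max_neighborhood)
  vnet <- build_virtual_network(net, sim, tau)
  cores <- mine_cores(vnet, min_core = min_core)
  complexes <- lapply(cores, function(core) {
    att <- select_attachments(net, core, sim)
    list(core = core, attachments = att, members = sort(c(core, att)))
  })
  # deduplicate identical member sets, first occurrence kept
  keys <- vapply(complexes, function(x) paste(x$members, collapse = "|"), "")
  complexes <- complexes[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  complexes <- complexes[order(keys)]
  new_complex_detection(complexes, net, igraph::ecount(vnet), beta, tau,
                        variant, min_core, cl)
}

new_complex_detection <- function(complexes, net, virtual_edges, beta, tau,
                                  variant, min_core, call) {
  structure(list(
    complexes = complexes,
    params = list(beta = beta, tau = tau, variant = variant,
                  min_core = min_core),
    n_vertices = igraph::vcount(net),
    n_edges = igraph::ecount(net),
    virtual_edges = virtual_edges,
    call = call
  ), class = "complex_detection")
}

#' Extract the predicted member-set catalog
#'
#' @param x a `complex_detection` object.
#' @return a `complex_catalog` of member sets (core and attachments pooled).
#' @export
predicted_catalog <- function(x) {
  stopifnot(inherits(x, "complex_detection"))
  as_complex_catalog(lapply(x$complexes, `[[`, "members"))
}

#' @export
print.complex_detection <- function(x, ...) {
  cat("Weak-ties core-attachment complex detection\n")
  cat("  network: ", x$n_vertices, " proteins, ", x$n_edges,
      " interactions; virtual network: ", x$virtual_edges, " edges\n", sep = "")
  cat("  parameters: beta = ", x$params$beta, ", tau = ", x$params$tau,
      ", bridgeness = ", x$params$variant, ", min core = ",
      x$params$min_core, "\n", sep = "")
  cat("  predicted complexes:", length(x$complexes), "\n")
  invisible(x)
}

#' @export
summary.complex_detection <- function(object, net = NULL, ...) {
  sizes <- vapply(object$complexes, function(z) length(z$members), 0L)
  core_sizes <- vapply(object$complexes, function(z) length(z$core), 0L)
  out <- list(
    n_complexes = length(object$complexes),
    params = object$params,
    size_summary = if (length(sizes)) summary(sizes) else NULL,
    core_size_summary = if (length(core_sizes)) summary(core_sizes) else NULL,
    n_attached = if (length(sizes)) sum(sizes - core_sizes) else 0L,
    densities = if (!is.null(net) && length(sizes))
      complex_stats(predicted_catalog(object), net)$density else NULL
  )
  class(out) <- "summary.complex_detection"
  out
}

#' @export
print.summary.complex_detection <- function(x, ...) {
  cat("Predicted complexes:", x$n_complexes, "\n")
  cat("Parameters: beta =", x$params$beta, "| tau =", x$params$tau,
      "| bridgeness =", x$params$variant, "| min core =", x$params$min_core, "\n")
  if (!is.null(x$size_summary)) {
    cat("Complex sizes:\n"); print(x$size_summary)
    cat("Core sizes:\n"); print(x$core_size_summary)
    cat("Attachment memberships:", x$n_attached, "\n")
  }
  if (!is.null(x$densities)) {
    cat("Original-network densities:\n"); print(summary(x$densities))
  }
  invisible(x)
}

#' Plot size and density distributions of a detection result
#'
#' Two base-graphics histograms: predicted complex sizes, and (when the
#' original network is supplied) complex densities on the original network.
#'
#' @param x a `complex_detection` object.
#' @param net optional original `igraph` graph for densities.
#' @param ... passed to [graphics::hist()].
#' @export
plot.complex_detection <- function(x, net = NULL, ...) {
  sizes <- vapply(x$complexes, function(z) length(z$members), 0L)
  if (length(sizes) == 0L) {
    warning("no complexes to plot", call. = FALSE)
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1L, if (is.null(net)) 1L else 2L))
  on.exit(graphics::par(op))
  graphics::hist(sizes, main = "Predicted complex sizes", xlab = "size", ...)
  if (!is.null(net)) {
    dens <- complex_stats(predicted_catalog(x), net)$density
    graphics::hist(dens, main = "Complex densities", xlab = "density",
                   xlim = c(0, 1), ...)
  }
  invisible(x)
}

#' Write predicted complexes
#'
#' One complex per line, core members first, then attachments, followed by a
#' `#core-size=k` comment token.
#'
#' @param x a `complex_detection` object.
#' @param sink file path or connection.
#' @export
write_predicted_complexes <- function(x, sink) {
  stopifnot(inherits(x, "complex_detection"))
  lines <- vapply(x$complexes, function(z) {
    paste(c(sort(z$core), sort(z$attachments),
            paste0("#core-size=", length(z$core))), collapse = " ")
  }, "")
  writeLines(lines, sink)
  invisible(NULL)
}

#' Sweep a detection parameter
#'
#' Re-runs the pipeline over a grid of `tau` or `beta` values, recording the
#' virtual-network edge count and the number of predicted complexes, plus
#' F-measure and coverage rate against a benchmark catalog when one is given.
#' The virtual edge count is non-increasing in `tau` on a fixed input.
#'
#' @param net an `igraph` graph with named vertices.
#' @param param `"tau"` or `"beta"`.
#' @param grid numeric vector of parameter values.
#' @param bench optional benchmark `complex_catalog`.
#' @param na_threshold neighborhood-affinity match threshold for the metrics.
#' @param ... fixed arguments forwarded to [detect_complexes()].
#' @return a data frame with one row per grid value.
#' @export
sweep_parameter <- function(net, param = c("tau", "beta"), grid,
                            bench = NULL, na_threshold = 0.2, ...) {
  param <- match.arg(param)
  rows <- lapply(grid, function(val) {
    args <- c(list(net = net), stats::setNames(list(val), param), list(...))
    fit <- do.call(detect_complexes, args)
    row <- data.frame(value = val, virtual_edges = fit$virtual_edges,
                      n_complexes = length(fit$complexes))
    if (!is.null(bench)) {
      ps <- predicted_catalog(fit)
      fm <- f_measure(ps, bench, t = na_threshold)
      row$f_measure <- fm$f_measure
      row$coverage_rate <- coverage_rate(bench, ps)
    }
    row
  })
  out <- do.call(rbind, rows)
  names(out)[1L] <- param
  out
}
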
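#' Maximum-clique size queries and maximal clique enumeration
#'
#' The bridgeness scores are built from three exact clique-size quantities:
#' `C_u`, the size of the largest clique containing vertex `u`; `C_uv`, the
#' size of the largest clique containing the edge `(u,v)`; and `C_{u\\v}`, the
#' size of the largest clique containing `u` once `v` is deleted from the
#' graph. All three are computed exactly by maximum-clique search restricted
#' to the relevant (closed) neighbourhood subgraph, which stays small in
#' sparse interaction networks.
#'
#' A guard refuses neighbourhoods larger than `max_neighborhood` vertices
#' rather than silently approximating.
#'
#' @param net an `igraph` graph with named vertices.
#' @param u,v vertex identifiers (names).
#' @param max_neighborhood refuse exact search above this neighbourhood size.
#' @return an integer clique size.
#' @name clique_sizes
NULL

#' @describeIn clique_sizes size of the largest clique containing vertex `u`
#'   (`>= 1`; an isolated vertex yields 1).
#' @export
max_clique_size_with_vertex <- function(net, u, max_neighborhood = 200L) {
  check_vertex(net, u)
  nbrs <- igraph::neighbors(net, u)$name
  clique_num_guarded(net, nbrs, max_neighborhood) + 1L
}

#' @describeIn clique_sizes size of the largest clique containing the edge
#'   `(u,v)` (`>= 2`).
#' @export
max_clique_size_with_edge <- function(net, u, v, max_neighborhood = 200L) {
  check_vertex(net, u); check_vertex(net, v)
  if (!igraph::are_adjacent(net, u, v)) {
    stop("(", u, ", ", v, ") is not an edge of the network", call. = FALSE)
  }
  common <- intersect(igraph::neighbors(net, u)$name,
                      igraph::neighbors(net, v)$name)
  clique_num_guarded(net, common, max_neighborhood) + 2L
}

#' @describeIn clique_sizes size of the largest clique containing `u` in the
#'   graph with `v` removed (`>= 1`; if deleting `v` isolates `u` the trivial
#'   clique `{u}` gives 1).
#' @export
max_clique_size_excluding <- function(net, u, v, max_neighborhood = 200L) {
  check_vertex(net, u); check_vertex(net, v)
  if (identical(u, v)) stop("u and v must differ", call. = FALSE)
  nbrs <- setdiff(igraph::neighbors(net, u)$name, v)
  # the deletion of v only matters inside u's neighbourhood
  clique_num_guarded(net, nbrs, max_neighborhood) + 1L
}

#' Enumerate maximal cliques
#'
#' All inclusion-maximal cliques of size at least `min_size`, each reported
#' once, in canonical order: members sorted within each clique, cliques sorted
#' lexicographically.
#'
#' @param net an `igraph` graph with named vertices.
#' @param min_size smallest clique size to report (`>= 1`).
#' @return a list of character vectors.
#' @export
enumerate_maximal_cliques <- function(net, min_size = 1L) {
  stopifnot(min_size >= 1L)
  if (igraph::vcount(net) == 0L) return(list())
  cl <- igraph::max_cliques(net, min = min_size)
  cl <- lapply(cl, function(x) sort(x$name))
  keys <- vapply(cl, paste, "", collapse = "|")
  cl[order(keys)]
}

# -- internal -----------------------------------------------------------------

check_vertex <- function(net, u) {
  if (!is.character(u) || length(u) != 1L || !(u %in% igraph::V(net)$name)) {
    stop("unknown vertex: ", u, call. = FALSE)
  }
  invisible(TRUE)
}

# size of the largest clique in the subgraph induced on `vids` (0 if empty)
clique_num_guarded <- function(net, vids, max_neighborhood) {
  if (length(vids) == 0L) return(0L)
  if (length(vids) > max_neighborhood) {
    stop("neighbourhood of size ", length(vids), " exceeds the exact-search ",
         "guard (", max_neighborhood, "); raise max_neighborhood explicitly",
         call. = FALSE)
  }
  sub <- igraph::induced_subgraph(net, vids)
  igraph::clique_num(sub)
}
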
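#' Jaccard similarity of two vertices' neighbourhoods
#'
#' Intersection over union of the two neighbour sets. Open neighbourhoods are
#' the default (a vertex is not its own neighbour); `closed = TRUE` adds each
#' endpoint to its own set, provided as a sensitivity switch. Returns 0 when
#' the union is empty (two isolated vertices).
#'
#' @param net an `igraph` graph with named vertices.
#' @param u,v vertex identifiers.
#' @param closed use closed neighbourhoods.
#' @return a value in `[0, 1]`.
#' @export
jaccard_similarity <- function(net, u, v, closed = FALSE) {
  check_vertex(net, u); check_vertex(net, v)
  nu <- igraph::neighbors(net, u)$name
  nv <- igraph::neighbors(net, v)$name
  if (closed) {
    nu <- union(nu, u)
    nv <- union(nv, v)
  }
  un <- length(union(nu, nv))
  if (un == 0L) return(0)
  length(intersect(nu, nv)) / un
}

#' Edge bridgeness
#'
#' Bridgeness quantifies how much an edge maintains global connectivity (a
#' weak tie between groups) rather than local cohesion (an edge inside a
#' dense group). Two variants are provided, both built from maximum-clique
#' sizes (see [clique_sizes]):
#'
#' * **reference**: `sqrt(C_u * C_v) / C_uv`. Every edge of a clique scores
#'   exactly 1, so the measure cannot tell a small clique's edges from a large
#'   one's.
#' * **weakties**: `(1 - J(u,v)) * sqrt(C_{u\\v} * C_{v\\u}) / C_uv`, where
#'   `J` is the open-neighbourhood Jaccard similarity. On an edge of an
#'   isolated m-clique this equals `2(m-1)/m^2`, decreasing with the clique
#'   size, and it is maximal on bridges joining dense groups.
#'
#' @param net an `igraph` graph with named vertices.
#' @param u,v endpoints of an edge of `net`.
#' @param max_neighborhood guard for the exact clique search.
#' @return a nonnegative real score.
#' @name bridgeness
NULL

#' @describeIn bridgeness the clique-ratio reference measure.
#' @export
bridgeness_reference <- function(net, u, v, max_neighborhood = 200L) {
  cuv <- max_clique_size_with_edge(net, u, v, max_neighborhood)
  cu <- max_clique_size_with_vertex(net, u, max_neighborhood)
  cv <- max_clique_size_with_vertex(net, v, max_neighborhood)
  sqrt(cu * cv) / cuv
}

#' @describeIn bridgeness the weak-ties measure with the Jaccard
#'   dissimilarity factor.
#' @export
bridgeness_weaktie <- function(net, u, v, max_neighborhood = 200L) {
  cuv <- max_clique_size_with_edge(net, u, v, max_neighborhood)
  cu_v <- max_clique_size_excluding(net, u, v, max_neighborhood)
  cv_u <- max_clique_size_excluding(net, v, u, max_neighborhood)
  j <- jaccard_similarity(net, u, v)
  (1 - j) * sqrt(cu_v * cv_u) / cuv
}

#' Score every edge of a network
#'
#' Computes a per-edge score table for one of three variants: the two
#' bridgeness measures, or the walk-polynomial topological similarity
#' ([walk_similarity] on the 0/1 adjacency matrix) restricted to edges. The
#' result drives the percolation experiments and the bridgeness-based edge
#' weighting.
#'
#' @param net an `igraph` graph with named vertices.
#' @param variant one of `"weakties"`, `"reference"`, `"similarity"`.
#' @param beta walk-downweighting parameter, used only by
#'   `variant = "similarity"`.
#' @param max_neighborhood guard for the exact clique search.
#' @return an `edge_scores` data frame with columns `u`, `v` (lexicographic
#'   within each row), `score`; attributes `variant` and `vertices`.
#' @export
score_all_edges <- function(net, variant = c("weakties", "reference", "similarity"),
                            beta = 0.618, max_neighborhood = 200L) {
  variant <- match.arg(variant)
  el <- edge_name_matrix(net)
  if (nrow(el) == 0L) {
    return(new_edge_scores(character(0), character(0), numeric(0),
                           variant, igraph::V(net)$name))
  }
  a <- pmin(el[, 1L], el[, 2L])
  b <- pmax(el[, 1L], el[, 2L])
  if (variant == "similarity") {
    sim <- walk_similarity(igraph::as_adjacency_matrix(net, sparse = TRUE),
                           beta = beta)
    score <- similarity_entries(sim, a, b)
  } else {
    # cache C_u once per vertex; each edge then needs only local searches
    cu <- vapply(igraph::V(net)$name, function(u)
      as.numeric(max_clique_size_with_vertex(net, u, max_neighborhood)), 0)
    m <- nrow(el)
    score <- numeric(m)
    for (i in seq_len(m)) {
      u <- a[i]; v <- b[i]
      cuv <- max_clique_size_with_edge(net, u, v, max_neighborhood)
      if (variant == "reference") {
        score[i] <- sqrt(cu[[u]] * cu[[v]]) / cuv
      } else {
        cu_v <- max_clique_size_excluding(net, u, v, max_neighborhood)
        cv_u <- max_clique_size_excluding(net, v, u, max_neighborhood)
        j <- jaccard_similarity(net, u, v)
        score[i] <- (1 - j) * sqrt(cu_v * cv_u) / cuv
      }
    }
  }
  new_edge_scores(a, b, as.numeric(score), variant, igraph::V(net)$name)
}

new_edge_scores <- function(u, v, score, variant, vertices) {
  structure(
    data.frame(u = u, v = v, score = score, stringsAsFactors = FALSE),
    variant = variant, vertices = vertices,
    class = c("edge_scores", "data.frame")
  )
}
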
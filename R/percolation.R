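#' Giant component fraction
#'
#' Fraction of vertices contained in the largest connected component.
#'
#' @param net an `igraph` graph with at least one vertex.
#' @return a value in `(0, 1]`.
#' @export
giant_component_fraction <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0L) stop("network has no vertices", call. = FALSE)
  max(igraph::components(net)$csize) / n
}

#' Normalized susceptibility
#'
#' `sum(s^2) / N` over all connected components except one largest component,
#' where `s` is a component size and `N` the vertex count. When several
#' components tie for largest, exactly one of them is excluded. Singleton
#' components count with `s = 1`. The statistic peaks sharply when a network
#' disintegrates, making it the standard order-parameter companion to the
#' giant-component fraction in edge percolation.
#'
#' @param net an `igraph` graph with at least one vertex.
#' @return a nonnegative real.
#' @export
susceptibility <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0L) stop("network has no vertices", call. = FALSE)
  cs <- igraph::components(net)$csize
  cs <- cs[-which.max(cs)]
  sum(as.numeric(cs)^2) / n
}

#' Score-ordered edge percolation experiment
#'
#' Removes edges in ascending or descending order of a per-edge score (ties
#' broken lexicographically by edge identity, or at random with
#' `tie_break = "random"`), in batches of `ceiling(step_fraction * |E|)`
#' edges, recording the giant-component fraction and the normalized
#' susceptibility after each batch, starting from the intact graph. Scores are
#' computed once on the intact graph and never refreshed during removal.
#'
#' If the weak-ties effect holds, removing edges in *ascending* similarity
#' order (the weakest ties first) disintegrates the network much faster than
#' descending order, with a sharp susceptibility peak at the transition.
#'
#' @param net an `igraph` graph with named vertices and at least one edge.
#' @param scores an `edge_scores` table covering exactly the edges of `net`.
#' @param order remove smallest scores first (`"ascending"`) or largest first.
#' @param step_fraction batch size as a fraction of the edge count.
#' @param tie_break `"lexicographic"` (deterministic) or `"random"`.
#' @return a data frame with columns `fraction_removed`, `giant_fraction`,
#'   `susceptibility`; attributes `order` and `variant`.
#' @export
percolation_experiment <- function(net, scores,
                                   order = c("ascending", "descending"),
                                   step_fraction = 0.01,
                                   tie_break = c("lexicographic", "random")) {
  order <- match.arg(order)
  tie_break <- match.arg(tie_break)
  stopifnot(step_fraction > 0, step_fraction <= 1)
  el <- edge_name_matrix(net)
  m <- nrow(el)
  if (m == 0L) stop("network has no edges", call. = FALSE)
  net_keys <- edge_keys(el[, 1L], el[, 2L])
  score_keys <- edge_keys(scores$u, scores$v)
  pos <- match(net_keys, score_keys)
  if (anyNA(pos) || length(score_keys) != m) {
    stop("score table does not match the network's edge set", call. = FALSE)
  }
  s <- scores$score[pos]
  tie <- switch(tie_break,
                lexicographic = rank(net_keys, ties.method = "first"),
                random = sample.int(m))
  ord <- order(if (order == "ascending") s else -s, tie)
  batch <- ceiling(step_fraction * m)
  g <- net
  res <- list(record_state(g, 0))
  removed <- 0L
  # delete by canonical key lookup on the shrinking graph
  del_keys <- net_keys[ord]
  while (removed < m) {
    take <- del_keys[(removed + 1L):min(removed + batch, m)]
    cur <- edge_name_matrix(g)
    cur_keys <- edge_keys(cur[, 1L], cur[, 2L])
    g <- igraph::delete_edges(g, which(cur_keys %in% take))
    removed <- removed + length(take)
    res[[length(res) + 1L]] <- record_state(g, removed / m)
  }
  out <- do.call(rbind, res)
  attr(out, "order") <- order
  attr(out, "variant") <- attr(scores, "variant")
  out
}

record_state <- function(g, frac) {
  data.frame(fraction_removed = frac,
             giant_fraction = giant_component_fraction(g),
             susceptibility = susceptibility(g))
}

#' Bridgeness versus similarity profile
#'
#' Groups edges into quantile bins of their topological similarity (the walk
#' polynomial on the 0/1 adjacency matrix, restricted to edges) and reports
#' the mean weak-tie bridgeness per bin. A decreasing profile is the
#' negative-correlation signature: the less similar two interacting proteins
#' are, the stronger the tie's bridging role.
#'
#' @param net an `igraph` graph with named vertices.
#' @param bins number of similarity quantile bins (`>= 2`).
#' @param beta walk-discount parameter for the similarity.
#' @return a data frame with columns `bin_center` (mean similarity in the
#'   bin), `mean_bridgeness`, `n_edges`; zero rows when the graph has no
#'   edges.
#' @export
bridgeness_similarity_profile <- function(net, bins = 10L, beta = 0.618) {
  stopifnot(bins >= 2L)
  if (igraph::ecount(net) == 0L) {
    return(data.frame(bin_center = numeric(0), mean_bridgeness = numeric(0),
                      n_edges = integer(0)))
  }
  simsc <- score_all_edges(net, "similarity", beta = beta)
  brsc <- score_all_edges(net, "weakties")
  stopifnot(identical(simsc$u, brsc$u), identical(simsc$v, brsc$v))
  qs <- unique(stats::quantile(simsc$score, probs = seq(0, 1, length.out = bins + 1L)))
  grp <- if (length(qs) > 2L) {
    cut(simsc$score, breaks = qs, include.lowest = TRUE)
  } else {
    factor(rep(1L, nrow(simsc)))
  }
  agg_sim <- tapply(simsc$score, grp, mean)
  agg_br <- tapply(brsc$score, grp, mean)
  n <- tapply(seq_len(nrow(simsc)), grp, length)
  keep <- !is.na(agg_sim)
  data.frame(bin_center = as.numeric(agg_sim[keep]),
             mean_bridgeness = as.numeric(agg_br[keep]),
             n_edges = as.integer(n[keep]))
}
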
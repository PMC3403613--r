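#' Generate a planted core-attachment network
#'
#' Emulates the core-attachment organization of protein complexes: each
#' planted complex is a dense core clique plus peripheral attachment vertices,
#' each attachment linked to `ceiling(attachment_link_fraction * core_size)`
#' randomly chosen core members. Optional bridge edges connect random pairs of
#' distinct cores (the weak ties), and background noise edges are added
#' independently with probability `background_noise_prob` over the remaining
#' non-adjacent pairs. The generator is fully reproducible from `seed` and
#' never mutates the global RNG state.
#'
#' @param complex_count number of planted complexes.
#' @param core_size integer range `c(min, max)` (or a single size) from which
#'   each core's size is drawn uniformly.
#' @param attachments_per_complex number of attachment vertices per complex.
#' @param attachment_link_fraction fraction of core members each attachment
#'   connects to, in `(0, 1]`.
#' @param background_noise_prob independent probability of a spurious edge
#'   between any non-adjacent vertex pair, in `[0, 1)`.
#' @param bridge_edge_count number of core-to-core bridge edges.
#' @param seed integer seed.
#' @return a list with `network` (an `igraph` graph) and `truth` (a
#'   `complex_catalog` of the planted complexes, core plus attachments).
#' @export
planted_network <- function(complex_count = 20L,
                            core_size = c(4L, 8L),
                            attachments_per_complex = 2L,
                            attachment_link_fraction = 0.6,
                            background_noise_prob = 0,
                            bridge_edge_count = 0L,
                            seed = 1L) {
  stopifnot(complex_count >= 1L, attachments_per_complex >= 0L,
            attachment_link_fraction > 0, attachment_link_fraction <= 1,
            background_noise_prob >= 0, background_noise_prob < 1,
            bridge_edge_count >= 0L)
  if (length(core_size) == 1L) core_size <- rep(core_size, 2L)
  if (min(core_size) < 2L) {
    stop("core size must be at least 2", call. = FALSE)
  }
  with_seed(seed, {
    edges_u <- character(0); edges_v <- character(0)
    truth <- vector("list", complex_count)
    cores <- vector("list", complex_count)
    verts <- character(0)
    for (i in seq_len(complex_count)) {
      cs_range <- core_size[1L]:core_size[2L]
      cs <- cs_range[sample.int(length(cs_range), 1L)]
      core <- sprintf("C%02d_c%02d", i, seq_len(cs))
      atts <- if (attachments_per_complex > 0L)
        sprintf("C%02d_a%02d", i, seq_len(attachments_per_complex))
      else character(0)
      # core clique
      if (cs > 1L) {
        pr <- utils::combn(core, 2L)
        edges_u <- c(edges_u, pr[1L, ]); edges_v <- c(edges_v, pr[2L, ])
      }
      nlink <- ceiling(attachment_link_fraction * cs)
      for (a in atts) {
        tgt <- sample(core, nlink)
        edges_u <- c(edges_u, rep(a, nlink)); edges_v <- c(edges_v, tgt)
      }
      truth[[i]] <- c(core, atts)
      cores[[i]] <- core
      verts <- c(verts, core, atts)
    }
    # bridges between random pairs of distinct cores
    if (bridge_edge_count > 0L && complex_count >= 2L) {
      for (b in seq_len(bridge_edge_count)) {
        ij <- sample(complex_count, 2L)
        edges_u <- c(edges_u, sample(cores[[ij[1L]]], 1L))
        edges_v <- c(edges_v, sample(cores[[ij[2L]]], 1L))
      }
    }
    g <- igraph::simplify(igraph::graph_from_data_frame(
      data.frame(from = edges_u, to = edges_v, stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = verts, stringsAsFactors = FALSE)))
    # i.i.d. background noise over the remaining non-edges
    if (background_noise_prob > 0) {
      non <- nonedge_matrix(g)
      if (nrow(non) > 0L) {
        pick <- stats::runif(nrow(non)) < background_noise_prob
        if (any(pick)) {
          g <- igraph::add_edges(g, t(non[pick, , drop = FALSE]))
        }
      }
    }
    names(truth) <- sprintf("planted%02d", seq_len(complex_count))
    list(network = g, truth = as_complex_catalog(truth))
  })
}

#' Build the test graph of a complex catalog
#'
#' Vertices are all catalog members; edges connect every pair of proteins
#' co-occurring in at least one complex (a union of cliques). This is the
#' standard robustness benchmark: each complex is a clique of its test graph.
#'
#' @param catalog a nonempty `complex_catalog`.
#' @return an `igraph` graph.
#' @export
test_graph_from_catalog <- function(catalog) {
  stopifnot(length(catalog) > 0L)
  verts <- unique(unlist(catalog))
  pairs <- lapply(catalog, function(members) {
    members <- unique(members)
    if (length(members) < 2L) return(NULL)
    t(utils::combn(members, 2L))
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::add_vertices(g, length(verts), name = verts)
    return(g)
  }
  igraph::simplify(igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1L], to = pairs[, 2L], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE)))
}

#' Randomly alter a graph by edge deletion and addition
#'
#' Deletes `floor(del_percent/100 * |E|)` uniformly chosen edges, then adds
#' `floor(add_percent/100 * |E|)` uniformly chosen non-edges, both percentages
#' relative to the *original* edge count. An added edge may recreate a deleted
#' one. The vertex set is preserved exactly; reproducible from `seed`.
#'
#' @param net an `igraph` graph with named vertices.
#' @param add_percent percentage of edges to add (`>= 0`).
#' @param del_percent percentage of edges to delete, in `[0, 100]`.
#' @param seed integer seed.
#' @return the altered `igraph` graph.
#' @export
alter_graph <- function(net, add_percent = 0, del_percent = 0, seed = 1L) {
  stopifnot(add_percent >= 0, del_percent >= 0, del_percent <= 100)
  m <- igraph::ecount(net)
  n_del <- floor(del_percent / 100 * m)
  n_add <- floor(add_percent / 100 * m)
  with_seed(seed, {
    g <- net
    if (n_del > 0L) {
      g <- igraph::delete_edges(g, sample(igraph::ecount(g), n_del))
    }
    if (n_add > 0L) {
      non <- nonedge_matrix(g)
      if (nrow(non) < n_add) {
        stop("requested ", n_add, " additions but only ", nrow(non),
             " non-edges are available", call. = FALSE)
      }
      pick <- sample(nrow(non), n_add)
      g <- igraph::add_edges(g, t(non[pick, , drop = FALSE]))
    }
    g
  })
}

#' Robustness experiment over altered test graphs
#'
#' For every combination of addition percentage, deletion percentage and
#' replicate: builds the altered test graph of `catalog`, runs
#' [detect_complexes()], and scores geometric accuracy and separation of the
#' predictions against the catalog.
#'
#' @param catalog the benchmark `complex_catalog` (defines the test graph and
#'   the annotated truth).
#' @param add_grid,del_grid percentage grids.
#' @param replicates replicate count per grid point.
#' @param seed integer master seed; each grid point and replicate gets a
#'   derived seed.
#' @param ... detector parameters forwarded to [detect_complexes()].
#' @return a data frame with columns `add`, `del`, `replicate`, `acc`, `sep`,
#'   `n_predicted`.
#' @export
robustness_experiment <- function(catalog, add_grid = seq(0, 100, by = 20),
                                  del_grid = 0, replicates = 3L, seed = 1L,
                                  ...) {
  tg <- test_graph_from_catalog(catalog)
  grid <- expand.grid(add = add_grid, del = del_grid,
                      replicate = seq_len(replicates))
  grid <- grid[order(grid$add, grid$del, grid$replicate), , drop = FALSE]
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    gp <- grid[r, ]
    sub_seed <- (seed + 7919L * r) %% .Machine$integer.max
    ag <- alter_graph(tg, add_percent = gp$add, del_percent = gp$del,
                      seed = sub_seed)
    fit <- detect_complexes(ag, ...)
    ps <- predicted_catalog(fit)
    ga <- geometric_accuracy(catalog, ps)
    sp <- separation(catalog, ps)
    data.frame(add = gp$add, del = gp$del, replicate = gp$replicate,
               acc = ga$acc, sep = sp$sep, n_predicted = length(ps))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# -- internal -----------------------------------------------------------------

# all non-adjacent unordered vertex pairs (no self-loops), as an index matrix
nonedge_matrix <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  all_pairs <- t(utils::combn(n, 2L))
  adj <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  present <- adj[all_pairs] > 0
  all_pairs[!present, , drop = FALSE]
}

# evaluate expr with a local, restored-on-exit RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
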
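# small named graphs used across the tests

named_complete_graph <- function(m, prefix = "v") {
  g <- igraph::make_full_graph(m, directed = FALSE)
  igraph::set_vertex_attr(g, "name", value = sprintf("%s%02d", prefix, seq_len(m)))
}

# two K_m joined by a single bridge edge a01 -- b01
barbell_graph <- function(m) {
  g <- igraph::disjoint_union(named_complete_graph(m, "a"),
                              named_complete_graph(m, "b"))
  igraph::add_edges(g, c("a01", "b01"))
}

random_named_graph <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::set_vertex_attr(g, "name", value = sprintf("v%02d", seq_len(n)))
}

graph_from_named_edges <- function(edges, isolated = character(0)) {
  # edges: character vector like c("a","b", "b","c") taken pairwise
  em <- matrix(edges, ncol = 2L, byrow = TRUE)
  verts <- unique(c(as.vector(em), isolated))
  igraph::graph_from_data_frame(
    data.frame(from = em[, 1L], to = em[, 2L], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE))
}

# hand-constructed walk_similarity object over the given vertices
fake_similarity <- function(vertices, entries, beta = 0.618) {
  # entries: data.frame(u, v, s)
  n <- length(vertices)
  m <- matrix(0, n, n, dimnames = list(vertices, vertices))
  for (r in seq_len(nrow(entries))) {
    m[entries$u[r], entries$v[r]] <- entries$s[r]
    m[entries$v[r], entries$u[r]] <- entries$s[r]
  }
  structure(list(mat = Matrix::Matrix(m, sparse = TRUE), beta = beta,
                 source = "weighted"),
            class = "walk_similarity")
}

sorted_member_keys <- function(catalog) {
  sort(vapply(catalog, function(x) paste(sort(x), collapse = "|"), ""))
}
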
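test_that("virtual network thresholding is inclusive and vertex-preserving", {
  net <- graph_from_named_edges(c("a", "b", "b", "c", "a", "c"))
  sim <- fake_similarity(c("a", "b", "c"),
                         data.frame(u = c("a", "a", "b"),
                                    v = c("b", "c", "c"),
                                    s = c(0.5, 0.1, 0.4)))
  v1 <- build_virtual_network(net, sim, 0.3)
  expect_setequal(igraph::V(v1)$name, c("a", "b", "c"))
  el <- igraph::as_edgelist(v1)
  keys <- sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  expect_identical(keys, c("a b", "b c"))

  v0 <- build_virtual_network(net, sim, 0)
  expect_equal(igraph::ecount(v0), 3L)

  vhi <- build_virtual_network(net, sim, 0.9)
  expect_equal(igraph::ecount(vhi), 0L)
  expect_equal(igraph::vcount(vhi), 3L)

  bad_sim <- fake_similarity(c("a", "b", "z"),
                             data.frame(u = "a", v = "b", s = 1))
  expect_error(build_virtual_network(net, bad_sim, 0.1), "vertex set")
})

test_that("core mining returns canonical maximal cliques above the size floor", {
  vnet <- graph_from_named_edges(
    c("a", "b", "a", "c", "b", "c", "b", "d", "c", "d"))
  expect_identical(mine_cores(vnet, 3L),
                   list(c("a", "b", "c"), c("b", "c", "d")))
  expect_identical(mine_cores(named_complete_graph(5), 3L),
                   list(sprintf("v%02d", 1:5)))
  edgeless <- igraph::add_vertices(igraph::make_empty_graph(0, directed = FALSE),
                                   3, name = letters[1:3])
  expect_identical(mine_cores(edgeless, 3L), list())
})

test_that("closeness to a core uses the |U|+1 denominator", {
  sim1 <- fake_similarity(c("u", "v"), data.frame(u = "v", v = "u", s = 0.7))
  expect_equal(closeness_to_core("v", "u", sim1), 0.35)

  sim2 <- fake_similarity(c("a", "b", "v"),
                          data.frame(u = c("v", "v"), v = c("a", "b"),
                                     s = c(0.6, 0.6)))
  expect_equal(closeness_to_core("v", c("a", "b"), sim2), 0.4)

  sim3 <- fake_similarity(c("a", "b", "v"),
                          data.frame(u = "a", v = "b", s = 0.9))
  expect_equal(closeness_to_core("v", c("a", "b"), sim3), 0)
})

test_that("attachment selection applies the printed average-closeness rule", {
  # core {a,b}; candidates c (cl = 0.4) and d (cl = 0.1167);
  # acl = (0.4 + 0.1167)/(2 + 2) ~ 0.1292, so only c is selected
  net <- graph_from_named_edges(c("a", "b", "a", "c", "b", "d"))
  sim <- fake_similarity(c("a", "b", "c", "d"),
                         data.frame(u = c("c", "c", "d", "d"),
                                    v = c("a", "b", "a", "b"),
                                    s = c(0.6, 0.6, 0.35, 0.0001)))
  expect_identical(select_attachments(net, c("a", "b"), sim), "c")

  # no candidate outside the core
  iso <- graph_from_named_edges(c("a", "b"))
  expect_identical(select_attachments(iso, c("a", "b"), sim1 <- fake_similarity(
    c("a", "b"), data.frame(u = "a", v = "b", s = 1))), character(0))

  # a single candidate with positive closeness is always selected
  net1 <- graph_from_named_edges(c("u", "v"))
  sim_1 <- fake_similarity(c("u", "v"), data.frame(u = "u", v = "v", s = 0.2))
  expect_identical(select_attachments(net1, "u", sim_1), "v")
})

test_that("detection recovers planted complexes exactly on clean input", {
  pn <- planted_network(complex_count = 6L, core_size = c(4L, 6L),
                        attachments_per_complex = 2L, seed = 2L)
  fit <- detect_complexes(pn$network)
  ps <- predicted_catalog(fit)
  # every planted complex is matched at affinity >= 0.5
  for (b in pn$truth) {
    affs <- vapply(ps, neighborhood_affinity, 0, b = b)
    expect_gte(max(affs), 0.5)
  }
  expect_equal(f_measure(ps, pn$truth)$f_measure, 1)
  # cores are cliques of the virtual network and attachments touch their core
  for (cx in fit$complexes) {
    for (a in cx$attachments) {
      nb <- igraph::neighbors(pn$network, a)$name
      expect_gt(length(intersect(nb, cx$core)), 0L)
    }
  }
})

test_that("edgeless input yields an empty catalog", {
  edgeless <- igraph::add_vertices(igraph::make_empty_graph(0, directed = FALSE),
                                   4, name = letters[1:4])
  fit <- detect_complexes(edgeless)
  expect_length(fit$complexes, 0L)
})

test_that("a barbell separates into its two cliques once tau exceeds the bridge scale", {
  bb <- barbell_graph(6)
  fit <- detect_complexes(bb, tau = 0.15)
  expect_length(fit$complexes, 2L)
  cores <- lapply(fit$complexes, `[[`, "core")
  expect_identical(sorted_member_keys(as_complex_catalog(cores)),
                   sort(c(paste(sprintf("a%02d", 1:6), collapse = "|"),
                          paste(sprintf("b%02d", 1:6), collapse = "|"))))
  # the opposite bridge endpoint may join as a lone attachment, but the two
  # cliques are never merged into one complex
  for (cx in fit$complexes) {
    expect_lte(length(cx$members), 7L)
  }
})

test_that("detection is equivariant under vertex relabeling", {
  pn <- planted_network(complex_count = 4L, core_size = 5L,
                        attachments_per_complex = 1L,
                        bridge_edge_count = 3L, seed = 8L)
  g <- pn$network
  verts <- igraph::V(g)$name
  set.seed(99)
  relabel <- stats::setNames(sprintf("q%03d", sample(length(verts))), verts)
  g2 <- igraph::set_vertex_attr(g, "name", value = unname(relabel[verts]))

  ps1 <- predicted_catalog(detect_complexes(g))
  ps2 <- predicted_catalog(detect_complexes(g2))
  ps1_mapped <- lapply(ps1, function(m) sort(unname(relabel[m])))
  expect_identical(sorted_member_keys(as_complex_catalog(ps1_mapped)),
                   sorted_member_keys(ps2))
})

test_that("raising tau never adds virtual edges and the sweep reports it", {
  pn <- planted_network(complex_count = 5L, core_size = c(4L, 6L),
                        attachments_per_complex = 1L,
                        bridge_edge_count = 4L, seed = 4L)
  sw <- sweep_parameter(pn$network, "tau", c(0, 0.02, 0.1, 0.5, 1, 2),
                        bench = pn$truth)
  expect_true(all(diff(sw$virtual_edges) <= 0))
  expect_true(all(c("tau", "virtual_edges", "n_complexes", "f_measure",
                    "coverage_rate") %in% names(sw)))

  sb <- sweep_parameter(pn$network, "beta", c(0.3, 0.618, 1.2))
  expect_equal(nrow(sb), 3L)
})
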
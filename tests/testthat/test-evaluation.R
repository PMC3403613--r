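test_that("neighborhood affinity matches its closed form", {
  expect_equal(neighborhood_affinity(letters[1:4], letters[1:4]), 1)
  expect_equal(neighborhood_affinity(c("a", "b", "c", "d"),
                                     c("c", "d", "e", "f")), 0.25)
  expect_equal(neighborhood_affinity(c("a", "b"), c("x", "y")), 0)
  expect_error(neighborhood_affinity(character(0), "a"), "nonempty")
})

test_that("match counts and F-measure follow the matching rule", {
  PS <- as_complex_catalog(list(c("A", "B"), c("C", "D")))
  BS <- as_complex_catalog(list(c("A", "B", "C")))
  mc <- match_counts(PS, BS, t = 0.2) # NA(AB, ABC) = 4/6
  expect_equal(unname(mc), c(1L, 1L))

  same <- as_complex_catalog(list(c("A", "B", "C"), c("D", "E")))
  expect_equal(unname(match_counts(same, same, t = 0.99)), c(2L, 2L))

  disj <- as_complex_catalog(list(c("Z1", "Z2")))
  expect_equal(unname(match_counts(disj, BS, t = 0.2)), c(0L, 0L))

  expect_equal(f_measure(same, same, 0.99)$f_measure, 1)
  expect_equal(f_measure(disj, BS)$f_measure, 0)
  # P = 0.5, R = 1 gives the harmonic mean 2/3
  PS2 <- as_complex_catalog(list(c("A", "B", "C"), c("Q1", "Q2", "Q3")))
  fm <- f_measure(PS2, as_complex_catalog(list(c("A", "B", "C"))), t = 0.5)
  expect_equal(fm$precision, 0.5)
  expect_equal(fm$recall, 1)
  expect_equal(fm$f_measure, 2 / 3)

  expect_warning(z <- f_measure(as_complex_catalog(list()), BS), "empty")
  expect_equal(z$f_measure, 0)
})

test_that("coverage rate sums best-match overlaps over benchmark membership", {
  BS <- as_complex_catalog(list(c("A", "B", "C"), c("C", "D")))
  PS <- as_complex_catalog(list(c("A", "B")))
  expect_equal(coverage_rate(BS, PS), 0.4)
  expect_equal(coverage_rate(BS, BS), 1)
  expect_equal(coverage_rate(BS, as_complex_catalog(list())), 0)
})

test_that("hypergeometric P-value matches exact combinatorics", {
  expect_equal(hypergeometric_pvalue(10, 5, 2, 2), 10 / 45)
  expect_equal(hypergeometric_pvalue(10, 5, 2, 0), 1)
  expect_error(hypergeometric_pvalue(10, 11, 2, 1), "inconsistent")
  expect_error(hypergeometric_pvalue(10, 5, 2, 3), "inconsistent")

  set.seed(31)
  for (rep in 1:25) {
    V <- sample(10:60, 1L)
    F_ <- sample(1:(V - 1L), 1L)
    C <- sample(1:min(V, 30L), 1L)
    kmax <- min(F_, C)
    k <- if (kmax == 0L) 0L else sample(0:kmax, 1L)
    got <- hypergeometric_pvalue(V, F_, C, k)
    want <- if (k == 0L) 1 else oracle_hypergeometric_tail(V, F_, C, k)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("enrichment reports the best group per complex without correction", {
  groups <- list(ribosome = sprintf("R%02d", 1:10),
                 polymerase = sprintf("P%02d", 1:8))
  catalog <- as_complex_catalog(list(sprintf("R%02d", 1:5),
                                     c("X1", "X2", "X3")))
  res <- complex_enrichment(catalog, groups, universe_size = 100,
                            cutoff = 0.01)
  expect_equal(nrow(res), 2L)
  expect_identical(res$best_group[1L], "ribosome")
  expect_true(res$significant[1L])
  expect_false(res$significant[2L])
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})

test_that("geometric accuracy and separation match hand matrices", {
  BSd <- as_complex_catalog(list(c("A", "B", "C"), c("D", "E")))
  ga <- geometric_accuracy(BSd, BSd)
  expect_equal(ga$sn, 1); expect_equal(ga$ppv, 1); expect_equal(ga$acc, 1)

  half <- as_complex_catalog(list(c("A", "B")))
  single <- as_complex_catalog(list(c("A", "B", "C", "D")))
  ga2 <- geometric_accuracy(single, half)
  expect_equal(ga2$sn, 0.5)
  expect_equal(ga2$ppv, 1)
  expect_equal(ga2$acc, sqrt(0.5))

  # overlapping benchmark complexes inflate column sums: PPV < 1 even for
  # perfect clusters
  BSo <- as_complex_catalog(list(c("A", "B"), c("B", "C")))
  ga3 <- geometric_accuracy(BSo, BSo)
  expect_lt(ga3$ppv, 1)

  sep1 <- separation(as_complex_catalog(list(c("A", "B"))),
                     as_complex_catalog(list(c("A", "B"))))
  expect_equal(sep1$sep, 1)

  # one benchmark complex split evenly into two clusters
  sep2 <- separation(as_complex_catalog(list(c("A", "B", "C", "D"))),
                     as_complex_catalog(list(c("A", "B"), c("C", "D"))))
  expect_equal(sep2$sep_co, 1)
  expect_equal(sep2$sep_cl, 0.5)
  expect_equal(sep2$sep, sqrt(0.5))

  sep0 <- separation(BSd, as_complex_catalog(list()))
  expect_equal(sep0$sep, 0)
})

test_that("all catalog metrics agree with double-loop reimplementations", {
  set.seed(77)
  universe <- sprintf("p%02d", 1:25)
  for (rep in 1:30) {
    BS <- random_catalog(sample(2:5, 1L), universe)
    PS <- random_catalog(sample(1:5, 1L), universe)
    t <- stats::runif(1, 0.1, 0.6)

    fm <- f_measure(PS, BS, t)
    ofm <- oracle_fmeasure(PS, BS, t)
    expect_equal(fm$f_measure, ofm$f_measure)
    expect_equal(fm$n_cp, ofm$n_cp)
    expect_equal(fm$n_cb, ofm$n_cb)

    expect_equal(overlap_matrix(BS, PS), oracle_overlap(BS, PS))
    expect_equal(coverage_rate(BS, PS), oracle_coverage(BS, PS))

    ga <- geometric_accuracy(BS, PS); oga <- oracle_accuracy(BS, PS)
    expect_equal(ga$sn, oga$sn)
    expect_equal(ga$ppv, oga$ppv)
    expect_equal(ga$acc, oga$acc)
    expect_true(ga$acc >= 0 && ga$acc <= 1)

    sp <- separation(BS, PS); osp <- oracle_separation(BS, PS)
    expect_equal(sp$sep_co, osp$sep_co)
    expect_equal(sp$sep_cl, osp$sep_cl)
    expect_equal(sp$sep, osp$sep)
    expect_true(sp$sep >= 0 && sp$sep <= 1)
  }
})

test_that("complex stats report induced size and density on the original graph", {
  net <- graph_from_named_edges(
    c("a", "b", "a", "c", "b", "c", "c", "d", "d", "e"),
    isolated = "z")
  st <- complex_stats(as_complex_catalog(list(
    c("a", "b", "c"),      # triangle: density 1
    c("a", "b", "c", "d"), # 4 members, 4 induced edges: 4/6
    c("d", "e"),           # single edge: 1
    "z"                    # singleton: flagged 0
  )), net)
  expect_equal(st$density, c(1, 4 / 6, 1, 0))
  expect_identical(st$singleton, c(FALSE, FALSE, FALSE, TRUE))
  expect_error(complex_stats(as_complex_catalog(list("nope")), net),
               "outside")
})

test_that("the combined evaluation report is internally consistent", {
  BS <- as_complex_catalog(list(c("A", "B", "C"), c("D", "E", "F")))
  PS <- as_complex_catalog(list(c("A", "B", "C"), c("D", "E"), c("X", "Y")))
  rep <- evaluate_complexes(PS, BS, t = 0.2)
  expect_equal(rep$f_measure,
               2 * rep$precision * rep$recall / (rep$precision + rep$recall))
  expect_equal(rep$acc^2, rep$sn * rep$ppv)
  expect_equal(rep$sep^2, rep$sep_co * rep$sep_cl)
  expect_output(print(rep), "F-measure")
})
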
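#' Neighborhood affinity of two member sets
#'
#' `NA(p, b) = |p intersect b|^2 / (|p| * |b|)`: the standard squared-overlap
#' score used to decide whether a predicted and a benchmark complex match.
#'
#' @param p,b nonempty character vectors (member sets).
#' @return a value in `[0, 1]`.
#' @export
neighborhood_affinity <- function(p, b) {
  p <- unique(p); b <- unique(b)
  if (length(p) == 0L || length(b) == 0L) {
    stop("member sets must be nonempty", call. = FALSE)
  }
  length(intersect(p, b))^2 / (length(p) * length(b))
}

#' Matched prediction and benchmark counts
#'
#' `N_cp` is the number of predictions matching at least one benchmark
#' complex at affinity threshold `t`; `N_cb` the number of benchmark
#' complexes matched by at least one prediction.
#'
#' @param PS predicted `complex_catalog`.
#' @param BS benchmark `complex_catalog`.
#' @param t neighborhood-affinity threshold in `(0, 1]`.
#' @return named numeric vector `c(n_cp = ..., n_cb = ...)`.
#' @export
match_counts <- function(PS, BS, t = 0.2) {
  stopifnot(t > 0, t <= 1)
  if (length(PS) == 0L || length(BS) == 0L) return(c(n_cp = 0L, n_cb = 0L))
  na_mat <- outer(seq_along(PS), seq_along(BS),
                  Vectorize(function(i, j) neighborhood_affinity(PS[[i]], BS[[j]])))
  hit <- na_mat >= t
  c(n_cp = sum(rowSums(hit) > 0L), n_cb = sum(colSums(hit) > 0L))
}

#' F-measure between predicted and benchmark catalogs
#'
#' Precision is the fraction of predictions matching some benchmark complex,
#' recall the fraction of benchmark complexes matched by some prediction, and
#' the F-measure their harmonic mean (0 when both are 0).
#'
#' @inheritParams match_counts
#' @return a list with `precision`, `recall`, `f_measure`, `n_cp`, `n_cb`.
#' @export
f_measure <- function(PS, BS, t = 0.2) {
  if (length(PS) == 0L || length(BS) == 0L) {
    warning("empty catalog: F-measure defined as 0", call. = FALSE)
    return(list(precision = 0, recall = 0, f_measure = 0, n_cp = 0L, n_cb = 0L))
  }
  mc <- match_counts(PS, BS, t)
  p <- mc[["n_cp"]] / length(PS)
  r <- mc[["n_cb"]] / length(BS)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f_measure = f,
       n_cp = mc[["n_cp"]], n_cb = mc[["n_cb"]])
}

#' Overlap matrix between benchmark and predicted catalogs
#'
#' `T[i, j]` is the number of proteins shared between the `i`-th benchmark
#' complex and the `j`-th predicted cluster.
#'
#' @inheritParams match_counts
#' @return an integer matrix, `|BS|` rows by `|PS|` columns.
#' @export
overlap_matrix <- function(BS, PS) {
  n <- length(BS); m <- length(PS)
  T <- matrix(0L, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    T[i, j] <- length(intersect(unique(BS[[i]]), unique(PS[[j]])))
  }
  T
}

#' Coverage rate
#'
#' `sum_i max_j T_ij / sum_i N_i`: the fraction of benchmark-complex
#' membership recovered by each benchmark complex's best-matching prediction.
#'
#' @inheritParams match_counts
#' @return a value in `[0, 1]`; 0 when `PS` is empty.
#' @export
coverage_rate <- function(BS, PS) {
  stopifnot(length(BS) > 0L)
  sizes <- vapply(BS, function(b) length(unique(b)), 0L)
  if (length(PS) == 0L) return(0)
  T <- overlap_matrix(BS, PS)
  sum(apply(T, 1L, max)) / sum(sizes)
}

#' Hypergeometric enrichment P-value
#'
#' Probability of observing at least `k` members of a functional group of
#' size `group_size` in a complex of size `complex_size` drawn from a network
#' of `universe_size` proteins: the upper tail of the hypergeometric
#' distribution, computed on the log scale via [stats::phyper()].
#'
#' @param universe_size number of proteins in the network.
#' @param group_size size of the functional group (`<= universe_size`).
#' @param complex_size size of the complex.
#' @param k observed overlap (`<= min(group_size, complex_size)`).
#' @return a P-value in `[0, 1]` (`k = 0` gives exactly 1).
#' @export
hypergeometric_pvalue <- function(universe_size, group_size, complex_size, k) {
  if (group_size > universe_size || complex_size > universe_size ||
      k > min(group_size, complex_size) || k < 0) {
    stop("inconsistent hypergeometric counts", call. = FALSE)
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, group_size, universe_size - group_size, complex_size,
                lower.tail = FALSE)
}

#' Functional enrichment of predicted complexes
#'
#' For each complex, tests every annotation group by the hypergeometric
#' upper-tail P-value and reports the best (smallest) one. No
#' multiple-testing correction is applied; a complex is flagged significant
#' when its best P-value is below `cutoff`.
#'
#' @param catalog a `complex_catalog` of predictions.
#' @param groups annotation groups from [read_annotation_groups()] (named list
#'   of member vectors).
#' @param universe_size size of the protein universe (defaults to the union
#'   of catalog and group members).
#' @param cutoff significance cutoff on the P-value.
#' @return a data frame with one row per complex: `complex`, `size`,
#'   `best_group`, `overlap`, `p_value`, `significant`.
#' @export
complex_enrichment <- function(catalog, groups,
                               universe_size = NULL, cutoff = 0.01) {
  if (is.null(universe_size)) {
    universe_size <- length(unique(c(unlist(catalog), unlist(groups))))
  }
  nm <- names(catalog)
  if (is.null(nm)) nm <- paste0("complex", seq_along(catalog))
  rows <- lapply(seq_along(catalog), function(i) {
    members <- unique(catalog[[i]])
    best <- list(group = NA_character_, k = 0L, p = 1)
    for (g in names(groups)) {
      grp <- unique(groups[[g]])
      if (length(grp) > universe_size) next
      k <- length(intersect(members, grp))
      p <- hypergeometric_pvalue(universe_size, length(grp),
                                 length(members), k)
      if (p < best$p) best <- list(group = g, k = k, p = p)
    }
    data.frame(complex = nm[i], size = length(members),
               best_group = best$group, overlap = best$k, p_value = best$p,
               significant = best$p < cutoff, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Clustering-wise sensitivity, positive predictive value, and accuracy
#'
#' From the overlap matrix `T` of benchmark (rows) versus clusters (columns):
#' `Sn = sum_i max_j T_ij / sum_i N_i`, `PPV = sum_j max_i T_ij / sum_j
#' sum_i T_ij`, and the geometric accuracy `ACC = sqrt(Sn * PPV)`. Clusters
#' sharing no member with any benchmark complex (zero column sums) contribute
#' nothing to either side of the PPV ratio.
#'
#' @param BS benchmark (annotated) `complex_catalog`.
#' @param clusters predicted `complex_catalog`.
#' @return a list with `sn`, `ppv`, `acc`.
#' @export
geometric_accuracy <- function(BS, clusters) {
  sizes <- vapply(BS, function(b) length(unique(b)), 0L)
  if (length(clusters) == 0L || length(BS) == 0L) {
    return(list(sn = 0, ppv = 0, acc = 0))
  }
  T <- overlap_matrix(BS, clusters)
  sn <- sum(apply(T, 1L, max)) / sum(sizes)
  colsum <- colSums(T)
  nz <- colsum > 0
  ppv <- if (any(nz)) sum(apply(T[, nz, drop = FALSE], 2L, max)) / sum(colsum[nz]) else 0
  list(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

#' Geometrical separation
#'
#' `Sep_ij` is the product of the row-normalized and column-normalized
#' overlap matrix entries; `Sep_co` averages the total over benchmark
#' complexes, `Sep_cl` over clusters, and `Sep` is their geometric mean.
#' Zero-sum rows or columns contribute 0.
#'
#' @inheritParams geometric_accuracy
#' @return a list with `sep_co`, `sep_cl`, `sep`.
#' @export
separation <- function(BS, clusters) {
  if (length(clusters) == 0L || length(BS) == 0L) {
    return(list(sep_co = 0, sep_cl = 0, sep = 0))
  }
  T <- overlap_matrix(BS, clusters)
  rs <- rowSums(T); cs <- colSums(T)
  frow <- sweep(T, 1L, ifelse(rs > 0, rs, 1), "/")
  fcol <- sweep(T, 2L, ifelse(cs > 0, cs, 1), "/")
  sep_ij <- frow * fcol
  total <- sum(sep_ij)
  sep_co <- total / nrow(T)
  sep_cl <- total / ncol(T)
  list(sep_co = sep_co, sep_cl = sep_cl, sep = sqrt(sep_co * sep_cl))
}

#' Size and density of each complex on the original network
#'
#' Density is `2 |E(members)| / (|members| (|members| - 1))` on the induced
#' subgraph of the original network; a singleton complex gets density 0 and
#' is flagged.
#'
#' @param catalog a `complex_catalog`.
#' @param net the original `igraph` graph (must contain all members).
#' @return a data frame with columns `complex`, `size`, `density`,
#'   `singleton`.
#' @export
complex_stats <- function(catalog, net) {
  verts <- igraph::V(net)$name
  nm <- names(catalog)
  if (is.null(nm)) nm <- paste0("complex", seq_along(catalog))
  rows <- lapply(seq_along(catalog), function(i) {
    members <- unique(catalog[[i]])
    if (!all(members %in% verts)) {
      stop("complex ", nm[i], " has members outside the network", call. = FALSE)
    }
    k <- length(members)
    if (k < 2L) {
      return(data.frame(complex = nm[i], size = k, density = 0,
                        singleton = TRUE, stringsAsFactors = FALSE))
    }
    ne <- igraph::ecount(igraph::induced_subgraph(net, members))
    data.frame(complex = nm[i], size = k,
               density = 2 * ne / (k * (k - 1)), singleton = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full evaluation report
#'
#' Bundles the match-based F-measure, coverage rate, geometric accuracy and
#' separation of a predicted catalog against a benchmark.
#'
#' @inheritParams match_counts
#' @return an `evaluation_report` list with fields `n_cp`, `n_cb`,
#'   `precision`, `recall`, `f_measure`, `coverage_rate`, `sn`, `ppv`, `acc`,
#'   `sep_co`, `sep_cl`, `sep`, `t`.
#' @export
evaluate_complexes <- function(PS, BS, t = 0.2) {
  fm <- f_measure(PS, BS, t)
  ga <- geometric_accuracy(BS, PS)
  sp <- separation(BS, PS)
  out <- c(fm[c("n_cp", "n_cb", "precision", "recall", "f_measure")],
           list(coverage_rate = coverage_rate(BS, PS)),
           ga, sp, list(t = t))
  class(out) <- "evaluation_report"
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Matched: %d predictions, %d benchmark complexes (t = %g)\n",
              x$n_cp, x$n_cb, x$t))
  cat(sprintf("Precision %.4f | Recall %.4f | F-measure %.4f\n",
              x$precision, x$recall, x$f_measure))
  cat(sprintf("Coverage rate %.4f\n", x$coverage_rate))
  cat(sprintf("Sn %.4f | PPV %.4f | ACC %.4f\n", x$sn, x$ppv, x$acc))
  cat(sprintf("Sep_co %.4f | Sep_cl %.4f | Sep %.4f\n",
              x$sep_co, x$sep_cl, x$sep))
  invisible(x)
}
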
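#' Truncated walk-polynomial similarity
#'
#' Given a symmetric nonnegative matrix `M` (the 0/1 adjacency matrix, or the
#' bridgeness-derived weight matrix from [weight_from_bridgeness()]), the
#' similarity of a vertex pair is the beta-discounted sum of walk strengths
#' over walks of length at most 3:
#'
#' `S = M + beta * M^2 + beta^2 * M^3`
#'
#' With the 0/1 adjacency matrix `(M^k)_ij` counts walks of length `k`; with a
#' weight matrix each walk contributes the product of its edge weights. Short
#' walks dominate when `beta < 1`. The polynomial is truncated at cubic order;
#' vertices at graph distance greater than 3 always score 0. Diagonal entries
#' (closed walks) are computed but never consulted downstream.
#'
#' @param m a symmetric, nonnegative, square matrix (base or
#'   [Matrix][Matrix::Matrix-class]) with identical row/column names.
#' @param beta positive walk-discount parameter; 0.618 by default.
#' @return a `walk_similarity` object: a list with `mat` (sparse symmetric
#'   matrix), `beta`, and `source` (`"unweighted"` or `"weighted"`).
#' @export
walk_similarity <- function(m, beta = 0.618) {
  stopifnot(beta > 0)
  m <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  if (nrow(m) != ncol(m) || !Matrix::isSymmetric(m, check.attributes = FALSE)) {
    stop("input matrix must be square and symmetric", call. = FALSE)
  }
  if (nrow(m) > 0 && min(m@x, 0) < 0) {
    stop("input matrix must be nonnegative", call. = FALSE)
  }
  src <- if (length(m@x) == 0L || all(m@x %in% c(0, 1))) "unweighted" else "weighted"
  m2 <- m %*% m
  s <- m + beta * m2 + beta^2 * (m2 %*% m)
  s <- methods::as(s, "CsparseMatrix")
  structure(list(mat = s, beta = beta, source = src),
            class = "walk_similarity")
}

#' @export
print.walk_similarity <- function(x, ...) {
  cat("Walk similarity matrix (", x$source, "), ", nrow(x$mat), " vertices, beta = ",
      x$beta, "\n", sep = "")
  invisible(x)
}

#' Bridgeness-derived edge weights
#'
#' Turns a bridgeness score table into a symmetric weighted adjacency matrix
#' with entries `exp(-B(u,v))` on edges and 0 elsewhere. High-bridgeness
#' (weak-tie) edges therefore carry weights close to 0 and contribute little
#' walk strength, while cohesive intra-complex edges keep weights near 1.
#'
#' @param scores an `edge_scores` table from [score_all_edges()] with variant
#'   `"reference"` or `"weakties"`.
#' @return a sparse symmetric matrix over the network's full vertex set, all
#'   edge weights in `(0, 1]`.
#' @export
weight_from_bridgeness <- function(scores) {
  variant <- attr(scores, "variant")
  if (!variant %in% c("reference", "weakties")) {
    stop("scores must be a bridgeness table (reference or weakties), got: ",
         variant, call. = FALSE)
  }
  verts <- attr(scores, "vertices")
  n <- length(verts)
  i <- match(scores$u, verts)
  j <- match(scores$v, verts)
  w <- exp(-scores$score)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                       dims = c(n, n), dimnames = list(verts, verts))
}

#' Bridgeness-weighted pairwise similarity
#'
#' The composition used by the detection pipeline: score every edge's
#' bridgeness, weight edges by `exp(-B)`, then apply the truncated walk
#' polynomial. Deterministic for a fixed network.
#'
#' @param net an `igraph` graph with named vertices.
#' @param beta walk-discount parameter.
#' @param variant bridgeness variant feeding the weights.
#' @param max_neighborhood guard for the exact clique search.
#' @return a `walk_similarity` object with `source = "weighted"`.
#' @export
pairwise_similarity <- function(net, beta = 0.618,
                                variant = c("weakties", "reference"),
                                max_neighborhood = 200L) {
  variant <- match.arg(variant)
  scores <- score_all_edges(net, variant, max_neighborhood = max_neighborhood)
  w <- weight_from_bridgeness(scores)
  sim <- walk_similarity(w, beta = beta)
  sim$source <- "weighted"
  sim
}

#' Dump the positive entries of a similarity matrix
#'
#' Writes `u v score` TSV rows for the strictly positive upper-triangle
#' entries (diagonal excluded).
#'
#' @param sim a `walk_similarity` object.
#' @param sink file path or connection.
#' @export
write_similarity <- function(sim, sink) {
  m <- Matrix::triu(sim$mat, k = 1L)
  tm <- methods::as(methods::as(m, "CsparseMatrix"), "TsparseMatrix")
  keep <- tm@x > 0
  verts <- rownames(sim$mat)
  lines <- paste(verts[tm@i[keep] + 1L], verts[tm@j[keep] + 1L],
                 format(tm@x[keep], digits = 10, trim = TRUE), sep = "\t")
  writeLines(c("u\tv\tscore", lines), sink)
  invisible(NULL)
}

# -- internal -----------------------------------------------------------------

# extract S(u, v) for name vectors u, v
similarity_entries <- function(sim, u, v) {
  verts <- rownames(sim$mat)
  as.numeric(sim$mat[cbind(match(u, verts), match(v, verts))])
}
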
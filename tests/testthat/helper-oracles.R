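# Independent brute-force oracles. These deliberately avoid the package's own
# code paths (and igraph's clique routines): cliques are found by exhaustive
# enumeration over all vertex subsets, walk sums by explicit loops over vertex
# sequences, and the hypergeometric tail by exact big-integer arithmetic.

# --- exhaustive clique enumeration (n <= 14) ---------------------------------

# returns a list of integer vectors: every clique of the graph (incl. singletons)
oracle_all_cliques <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n >= 1L, n <= 14L)
  adj <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  bits <- bitwShiftL(1L, 0:(n - 1L))
  adjc <- integer(n) # closed-neighbourhood bitmasks
  for (v in seq_len(n)) {
    adjc[v] <- bits[v] + sum(bits[adj[v, ]])
  }
  out <- vector("list", 0L)
  for (s in seq_len(bitwShiftL(1L, n) - 1L)) {
    m <- which(bitwAnd(s, bits) != 0L)
    if (all(bitwAnd(adjc[m], s) == s)) out[[length(out) + 1L]] <- m
  }
  out
}

oracle_max_size_with <- function(cliques, members) {
  sizes <- lengths(cliques)
  has <- vapply(cliques, function(cl) all(members %in% cl), TRUE)
  max(sizes[has])
}

oracle_max_size_excluding <- function(cliques, u, v) {
  sizes <- lengths(cliques)
  ok <- vapply(cliques, function(cl) (u %in% cl) && !(v %in% cl), TRUE)
  max(sizes[ok])
}

oracle_maximal_cliques <- function(cliques) {
  keys <- vapply(cliques, function(cl) paste(cl, collapse = ","), "")
  maximal <- vapply(seq_along(cliques), function(i) {
    !any(vapply(cliques, function(other)
      length(other) > length(cliques[[i]]) && all(cliques[[i]] %in% other),
      TRUE))
  }, TRUE)
  cliques[maximal]
}

# --- explicit walk-strength summation (n <= 8) -------------------------------

oracle_walk_similarity <- function(W, beta, i, j) {
  n <- nrow(W)
  s1 <- W[i, j]
  s2 <- 0
  for (x in seq_len(n)) s2 <- s2 + W[i, x] * W[x, j]
  s3 <- 0
  for (x in seq_len(n)) for (y in seq_len(n)) {
    s3 <- s3 + W[i, x] * W[x, y] * W[y, j]
  }
  s1 + beta * s2 + beta^2 * s3
}

# --- exact big-integer hypergeometric tail -----------------------------------
# integers as little-endian limb vectors in base 1e7 (limb products stay well
# below 2^53)

BI_BASE <- 1e7

bi_norm <- function(x) {
  i <- 1L
  while (i <= length(x)) {
    if (x[i] >= BI_BASE) {
      carry <- floor(x[i] / BI_BASE)
      x[i] <- x[i] - carry * BI_BASE
      if (i == length(x)) x <- c(x, 0)
      x[i + 1L] <- x[i + 1L] + carry
    }
    i <- i + 1L
  }
  while (length(x) > 1L && x[length(x)] == 0) x <- x[-length(x)]
  x
}

bi_add <- function(a, b) {
  n <- max(length(a), length(b))
  bi_norm(c(a, rep(0, n - length(a))) + c(b, rep(0, n - length(b))))
}

bi_mul <- function(a, b) {
  # limb products < 1e14 and at most ~6 accumulate per slot at the sizes used
  # here, staying well under 2^53 before the final carry pass
  out <- rep(0, length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  bi_norm(out)
}

bi_to_double <- function(x) sum(x * BI_BASE^(seq_along(x) - 1))

# list of big-integer binomials C(n, 0..n), built purely by Pascal additions
bi_pascal_row <- function(n) {
  row <- list(1)
  if (n == 0L) return(row)
  for (k in seq_len(n)) {
    new <- vector("list", k + 1L)
    new[[1L]] <- 1
    new[[k + 1L]] <- 1
    if (k > 1L) {
      for (j in 2:k) new[[j]] <- bi_add(row[[j - 1L]], row[[j]])
    }
    row <- new
  }
  row
}

# exact P(X >= k) for the hypergeometric distribution
oracle_hypergeometric_tail <- function(V, F_, C, k) {
  rowF <- bi_pascal_row(F_)
  rowR <- bi_pascal_row(V - F_)
  rowV <- bi_pascal_row(V)
  num <- 0
  for (i in k:min(F_, C)) {
    if (C - i > V - F_ || C - i < 0) next
    num <- bi_add(num, bi_mul(rowF[[i + 1L]], rowR[[C - i + 1L]]))
  }
  bi_to_double(num) / bi_to_double(rowV[[C + 1L]])
}

# --- direct double-loop metric reimplementations -----------------------------

oracle_na <- function(p, b) {
  p <- unique(p); b <- unique(b)
  length(intersect(p, b))^2 / (length(p) * length(b))
}

oracle_fmeasure <- function(PS, BS, t) {
  ncp <- 0L
  for (p in PS) {
    matched <- FALSE
    for (b in BS) if (oracle_na(p, b) >= t) matched <- TRUE
    if (matched) ncp <- ncp + 1L
  }
  ncb <- 0L
  for (b in BS) {
    matched <- FALSE
    for (p in PS) if (oracle_na(p, b) >= t) matched <- TRUE
    if (matched) ncb <- ncb + 1L
  }
  prec <- ncp / length(PS)
  rec <- ncb / length(BS)
  f <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(n_cp = ncp, n_cb = ncb, precision = prec, recall = rec, f_measure = f)
}

oracle_overlap <- function(BS, PS) {
  T <- matrix(0L, length(BS), length(PS))
  for (i in seq_along(BS)) for (j in seq_along(PS)) {
    shared <- 0L
    for (x in unique(BS[[i]])) if (x %in% PS[[j]]) shared <- shared + 1L
    T[i, j] <- shared
  }
  T
}

oracle_coverage <- function(BS, PS) {
  T <- oracle_overlap(BS, PS)
  best <- 0
  for (i in seq_along(BS)) best <- best + max(T[i, ])
  best / sum(vapply(BS, function(b) length(unique(b)), 0L))
}

oracle_accuracy <- function(BS, PS) {
  T <- oracle_overlap(BS, PS)
  Ni <- vapply(BS, function(b) length(unique(b)), 0L)
  sn <- sum(apply(T, 1L, max)) / sum(Ni)
  num <- 0; den <- 0
  for (j in seq_along(PS)) {
    cs <- sum(T[, j])
    if (cs > 0) {
      num <- num + max(T[, j])
      den <- den + cs
    }
  }
  ppv <- if (den > 0) num / den else 0
  list(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

oracle_separation <- function(BS, PS) {
  T <- oracle_overlap(BS, PS)
  total <- 0
  for (i in seq_along(BS)) for (j in seq_along(PS)) {
    rs <- sum(T[i, ]); cs <- sum(T[, j])
    if (rs > 0 && cs > 0) total <- total + (T[i, j] / rs) * (T[i, j] / cs)
  }
  sep_co <- total / length(BS)
  sep_cl <- total / length(PS)
  list(sep_co = sep_co, sep_cl = sep_cl, sep = sqrt(sep_co * sep_cl))
}

random_catalog <- function(n_complexes, universe, min_size = 2L, max_size = 6L) {
  as_complex_catalog(lapply(seq_len(n_complexes), function(i) {
    k <- sample(min_size:max_size, 1L)
    sample(universe, k)
  }))
}
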
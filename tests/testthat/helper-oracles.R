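# Independent oracles used to cross-check the implementation.
# These deliberately use naive loops / direct summation, not the package's
# own code paths.

# all-pairs kNN by exhaustive sort of the full distance matrix
oracle_knn <- function(coords, k) {
  n <- nrow(coords)
  idx <- matrix(0L, n, k); dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    d[i] <- Inf
    o <- order(d, seq_len(n))[seq_len(k)]
    idx[i, ] <- o; dst[i, ] <- d[o]
  }
  list(index = idx, dist = dst)
}

# cluster connectivity E(k,l) = sum_i sum_j c_ik a_ij c_jl by triple loop
oracle_connectivity <- function(C, A) {
  A <- as.matrix(A); C <- as.matrix(C)
  K <- ncol(C); n <- nrow(C)
  E <- matrix(0, K, K)
  for (k in seq_len(K)) for (l in seq_len(K)) {
    acc <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      acc <- acc + C[i, k] * A[i, j] * C[j, l]
    }
    E[k, l] <- acc
  }
  E
}

# maximum-connectivity Hamiltonian path by recursive brute force
oracle_best_path <- function(W) {
  K <- nrow(W)
  best <- list(score = -Inf, path = NULL)
  recurse <- function(path, remaining, score) {
    if (!length(remaining)) {
      if (score > best$score + 1e-12) best <<- list(score = score, path = path)
      return(invisible())
    }
    for (v in remaining) {
      recurse(c(path, v), setdiff(remaining, v),
              score + if (length(path)) W[path[length(path)], v] else 0)
    }
  }
  recurse(integer(0), seq_len(K), 0)
  best
}

# loss terms by direct elementwise summation
oracle_modularity <- function(C, A, denominator = "edges") {
  A <- as.matrix(A); C <- as.matrix(C)
  n <- nrow(A); d <- rowSums(A)
  den <- if (denominator == "nodes") 2 * n else sum(d)
  B <- A - outer(d, d) / den
  -sum(diag(t(C) %*% B %*% C)) / den
}

oracle_purity <- function(C, V) {
  C <- as.matrix(C); V <- as.matrix(V)
  K <- ncol(C); M <- ncol(V); n <- nrow(V)
  Vs <- matrix(0, K, M)
  for (k in seq_len(K)) {
    nk <- sum(C[, k])
    for (m in seq_len(M)) Vs[k, m] <- sum(C[, k] * V[, m]) / nk
  }
  acc <- 0
  for (j in seq_len(n)) for (m in seq_len(M)) {
    acc <- acc + (V[j, m] - sum(C[j, ] * Vs[, m]))^2
  }
  acc / (n * M)
}

oracle_collapse <- function(C) {
  C <- as.matrix(C)
  K <- ncol(C); n <- nrow(C)
  colsum <- numeric(K)
  for (k in seq_len(K)) colsum[k] <- sum(C[, k])
  sqrt(K) / (n * (sqrt(K) - 1)) * sqrt(sum(colsum^2))
}

# random row-stochastic matrix
random_stochastic <- function(n, K) {
  C <- matrix(stats::rexp(n * K), n, K)
  C / rowSums(C)
}

# small random spatial niche graph for loss/gradient tests
random_niche_graph <- function(n = 15, M = 4, k = 4) {
  xy <- matrix(stats::runif(n * 2), n, 2)
  knn <- build_knn(xy, k)
  A <- build_niche_adjacency(knn)
  V <- random_stochastic(n, M)
  list(A = A, A_norm = normalize_adjacency(A),
       S = normalize_adjacency(A) + Matrix::Diagonal(n), V = V, xy = xy)
}
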
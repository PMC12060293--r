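#' Niche-cluster connectivity network
#'
#' Collapses the niche graphs into a K x K cluster network:
#' \eqn{E(k,l) = \sum_i \sum_j c_{ik} a_{ij} c_{jl}}, summed over samples,
#' then normalized as \eqn{\tilde E(k,l) = E(k,l) / (\sum_i E(k,i) \cdot
#' \sum_i E(i,l))}. Entries whose row or column sum is zero are set to 0.
#'
#' @param C_list list of per-sample assignment matrices (see
#'   [assign_clusters()]), or a single matrix.
#' @param A_list matching list of per-sample adjacencies, or a single
#'   adjacency.
#' @return list of class \code{cluster_network} with raw \code{E} and
#'   normalized \code{E_norm}.
#' @export
cluster_connectivity <- function(C_list, A_list) {
  if (is.matrix(C_list) || inherits(C_list, "Matrix")) C_list <- list(C_list)
  if (!is.list(A_list)) A_list <- list(A_list)
  stopifnot(length(C_list) == length(A_list))
  K <- ncol(C_list[[1]])
  E <- matrix(0, K, K)
  for (s in seq_along(C_list)) {
    C <- as.matrix(C_list[[s]])
    stopifnot(nrow(C) == nrow(A_list[[s]]))
    E <- E + as.matrix(Matrix::crossprod(C, A_list[[s]] %*% C))
  }
  if (all(E == 0)) {
    stop("cluster connectivity is identically zero (degenerate clustering)",
         call. = FALSE)
  }
  rs <- rowSums(E); cs <- colSums(E)
  denom <- outer(rs, cs)
  En <- ifelse(denom > 0, E / denom, 0)
  structure(list(E = E, E_norm = En), class = "cluster_network")
}

#' Maximum-connectivity ordering of niche clusters
#'
#' Finds the Hamiltonian path \eqn{p_1 \to \dots \to p_K} maximizing
#' \eqn{\sum_{k=1}^{K-1} \tilde E(p_k, p_{k+1})} by exact search:
#' enumeration of all \eqn{K!/2} undirected paths for \eqn{K \le 8}, exact
#' Held-Karp dynamic programming for \eqn{9 \le K \le 16}. The diagonal is
#' ignored. Ties are broken lexicographically (on the orientation of the
#' path whose first endpoint is the smaller one).
#'
#' @param E_norm K x K nonnegative connectivity matrix.
#' @return integer permutation of \code{1:K}.
#' @export
optimal_ordering <- function(E_norm) {
  E_norm <- as.matrix(E_norm)
  K <- nrow(E_norm)
  stopifnot(K >= 2, ncol(E_norm) == K)
  W <- (E_norm + t(E_norm)) / 2   # path objective is orientation-free
  diag(W) <- 0
  path <- if (K <= 8) best_path_enum(W) else if (K <= 16) {
    best_path_heldkarp(W)
  } else {
    stop("exact ordering supported for K <= 16; got K = ", K, call. = FALSE)
  }
  if (path[1] > path[K]) path <- rev(path)
  path
}

path_score <- function(W, p) {
  sum(W[cbind(p[-length(p)], p[-1])])
}

# lexicographic enumeration of all permutations with first < last
best_path_enum <- function(W) {
  K <- nrow(W)
  perms <- all_permutations(K)
  best <- NULL; best_score <- -Inf
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    if (p[1] > p[K]) next                   # each undirected path once
    sc <- path_score(W, p)
    if (sc > best_score + 1e-15) {
      best_score <- sc; best <- p
    }
  }
  best
}

# all permutations of 1..n in lexicographic order (n small)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

# exact maximum-weight Hamiltonian path via Held-Karp over subsets
best_path_heldkarp <- function(W) {
  K <- nrow(W)
  nset <- bitwShiftL(1L, K)
  # dp[mask, v]: best score of a path visiting `mask` and ending at v
  dp <- matrix(-Inf, nset, K)
  parent <- matrix(0L, nset, K)
  for (v in seq_len(K)) dp[bitwShiftL(1L, v - 1L) + 1L, v] <- 0
  for (mask in seq_len(nset - 1L)) {
    for (v in seq_len(K)) {
      if (!bitwAnd(mask, bitwShiftL(1L, v - 1L))) next
      cur <- dp[mask + 1L, v]
      if (!is.finite(cur)) next
      for (u in seq_len(K)) {
        if (bitwAnd(mask, bitwShiftL(1L, u - 1L))) next
        nmask <- bitwOr(mask, bitwShiftL(1L, u - 1L))
        cand <- cur + W[v, u]
        if (cand > dp[nmask + 1L, u] + 1e-15) {
          dp[nmask + 1L, u] <- cand
          parent[nmask + 1L, u] <- v
        }
      }
    }
  }
  full <- nset - 1L
  end <- which.max(dp[full + 1L, ])
  path <- integer(K); path[K] <- end
  mask <- full
  for (i in rev(seq_len(K - 1L))) {
    prev <- parent[mask + 1L, path[i + 1L]]
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, path[i + 1L] - 1L)))
    path[i] <- prev
  }
  path
}

#' Niche-level NT scores
#'
#' The cluster at position \eqn{k} along the path gets the score
#' \eqn{s(p_k) = (k-1)/(K-1)}; each niche's NT score is its
#' assignment-weighted average \eqn{s_j = \sum_k c_{jk} s(k)}.
#'
#' @param C row-stochastic assignment matrix (or list of per-sample
#'   matrices).
#' @param ordering integer permutation from [optimal_ordering()].
#' @return numeric vector (or list of vectors) of niche scores in [0, 1].
#' @export
niche_nt_scores <- function(C, ordering) {
  K <- length(ordering)
  if (K == 1) {
    warning("single cluster: all NT scores are 0", call. = FALSE)
    cluster_scores <- 0
  } else {
    cluster_scores <- numeric(K)
    cluster_scores[ordering] <- (seq_len(K) - 1) / (K - 1)
  }
  score_one <- function(Cm) drop(as.matrix(Cm) %*% cluster_scores)
  if (is.list(C)) lapply(C, score_one) else score_one(C)
}

#' Cell-level NT scores
#'
#' Weighted average of the scores of every niche a cell belongs to:
#' \eqn{\tilde s_i = \sum_j w_{ij} s_j / \sum_j w_{ij}}.
#'
#' @param W sparse cells x niches association matrix.
#' @param niche_scores numeric vector of niche-level NT scores.
#' @return numeric vector of cell scores in [0, 1].
#' @export
cell_nt_scores <- function(W, niche_scores) {
  stopifnot(ncol(W) == length(niche_scores))
  tot <- Matrix::rowSums(W)
  stopifnot(all(tot > 0))                    # every cell anchors a niche
  drop(as.matrix(W %*% niche_scores)) / tot
}

#' Construct the niche trajectory from a fitted pooling model
#'
#' Pools the niche graphs into a cluster network, orders the clusters by
#' maximum connectivity, and scores every niche and cell along the
#' trajectory.
#'
#' @param fit a \code{trained_pooling} object.
#' @param network the \code{niche_network} it was trained on.
#' @return object of class \code{niche_trajectory}: \code{ordering},
#'   \code{cluster_scores}, \code{cluster_network}, per-sample
#'   \code{assignment}, \code{niche_scores} and \code{cell_scores} (named
#'   by cell id), and an \code{orientation} flag.
#' @export
build_trajectory <- function(fit, network) {
  C_list <- assign_clusters(fit, network)
  cn <- cluster_connectivity(C_list, lapply(network, `[[`, "A"))
  ordering <- optimal_ordering(cn$E_norm)
  K <- length(ordering)
  cluster_scores <- numeric(K)
  cluster_scores[ordering] <- (seq_len(K) - 1) / (K - 1)
  niche_scores <- niche_nt_scores(C_list, ordering)
  cell_scores <- lapply(seq_along(network), function(s) {
    sc <- cell_nt_scores(network[[s]]$W, niche_scores[[s]])
    names(sc) <- network[[s]]$cell_id
    sc
  })
  names(cell_scores) <- names(network)
  for (s in seq_along(network)) {
    names(niche_scores[[s]]) <- network[[s]]$cell_id
  }
  structure(list(ordering = ordering, cluster_scores = cluster_scores,
                 cluster_network = cn, assignment = C_list,
                 niche_scores = niche_scores, cell_scores = cell_scores,
                 orientation = 1L),
            class = "niche_trajectory")
}

#' @export
print.niche_trajectory <- function(x, ...) {
  cat("Niche trajectory over", length(x$ordering), "clusters\n")
  cat("ordering:", paste(x$ordering, collapse = " -> "), "\n")
  cat(sprintf("%d cells scored across %d sample(s); orientation %+d\n",
              sum(lengths(x$cell_scores)), length(x$cell_scores),
              x$orientation))
  invisible(x)
}

#' Orient a trajectory against a reference
#'
#' Trajectory direction is arbitrary (scores \eqn{s} and \eqn{1-s} are
#' equivalent). Given a per-cell reference (e.g. simulation ground truth),
#' all scores are flipped when their Spearman correlation with the
#' reference is negative. With no reference the trajectory is returned
#' unchanged.
#'
#' @param traj a \code{niche_trajectory}.
#' @param reference optional named numeric vector of per-cell reference
#'   values; matched to cells by name where names are present.
#' @return the (possibly flipped) \code{niche_trajectory}; the
#'   \code{orientation} field records \code{-1} after a flip.
#' @export
orient_trajectory <- function(traj, reference = NULL) {
  stopifnot(inherits(traj, "niche_trajectory"))
  if (is.null(reference)) return(traj)
  scores <- unlist(traj$cell_scores, use.names = FALSE)
  ids <- unlist(lapply(traj$cell_scores, names), use.names = FALSE)
  if (!is.null(names(reference)) && !is.null(ids)) {
    reference <- reference[ids]
  }
  rho <- suppressWarnings(
    stats::cor(scores, reference, method = "spearman"))
  if (!is.na(rho) && rho < 0) {
    traj$cluster_scores <- 1 - traj$cluster_scores
    traj$ordering <- rev(traj$ordering)
    traj$niche_scores <- lapply(traj$niche_scores, function(s) 1 - s)
    traj$cell_scores <- lapply(traj$cell_scores, function(s) 1 - s)
    traj$orientation <- -traj$orientation
  }
  traj
}
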
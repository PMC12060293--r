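#' k-nearest neighbours by Euclidean distance
#'
#' Exhaustive kNN within one sample. Distance ties are broken by cell index
#' so results are deterministic.
#'
#' @param coords numeric matrix (cells x dims), 2 or 3 columns.
#' @param k number of neighbours (excluding the cell itself). If the sample
#'   has \code{<= k} cells, \code{k} is clamped to \code{N - 1} with a
#'   warning (or an error if \code{on_small = "error"}).
#' @param on_small \code{"clamp"} (default) or \code{"error"}.
#' @return list with integer matrix \code{index} (N x k) and numeric matrix
#'   \code{dist} (N x k), each row sorted by nondecreasing distance.
#' @export
build_knn <- function(coords, k, on_small = c("clamp", "error")) {
  on_small <- match.arg(on_small)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (k < 1) stop("'k' must be a positive integer", call. = FALSE)
  if (n <= k) {
    if (on_small == "error") {
      stop(sprintf("sample has %d cells but k = %d neighbours requested",
                   n, k), call. = FALSE)
    }
    warning(sprintf("k = %d >= %d cells; clamping k to %d", k, n, n - 1L),
            call. = FALSE)
    k <- n - 1L
  }
  d <- as.matrix(stats::dist(coords))
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    di <- d[, i]
    di[i] <- Inf
    o <- order(di, seq_len(n))[seq_len(k)]  # ties broken by cell index
    idx[i, ] <- o
    dst[i, ] <- di[o]
  }
  list(index = idx, dist = dst, k = k)
}

#' Mutual-kNN niche adjacency
#'
#' Two niches are connected iff their anchoring cells are mutual k-nearest
#' neighbours: \eqn{a_{ij} = 1} iff \eqn{j \in kNN(i)} and
#' \eqn{i \in kNN(j)}.
#'
#' @param knn result of [build_knn()].
#' @return symmetric binary sparse adjacency (\code{Matrix::sparseMatrix}),
#'   zero diagonal.
#' @export
build_niche_adjacency <- function(knn) {
  n <- nrow(knn$index)
  directed <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = ncol(knn$index)),
    j = as.vector(t(knn$index)),
    x = 1, dims = c(n, n))
  a <- directed * Matrix::t(directed)         # elementwise AND
  methods::as(Matrix::drop0(a), "generalMatrix")
}

#' Gaussian cell-niche association weights
#'
#' A cell \eqn{i} belongs to niche \eqn{j} when it is the anchor or one of
#' the anchor's k nearest neighbours; for members
#' \eqn{w_{ij} = \exp(-d_{ij}^2 / \sigma_j^2)} where \eqn{d_{ij}} is the
#' distance from cell \eqn{i} to the anchoring cell of niche \eqn{j} and
#' \eqn{\sigma_j} is the distance from the anchor to its
#' \code{sigma_rank}-th nearest neighbour. Non-members get weight 0 (sparse).
#'
#' @param knn result of [build_knn()].
#' @param sigma_rank neighbour rank defining \eqn{\sigma_j} (default 20);
#'   clamped to the farthest available neighbour.
#' @return list with sparse \code{W} (cells x niches, values in (0, 1],
#'   anchors have weight exactly 1) and numeric \code{sigma}.
#' @export
cell_niche_weights <- function(knn, sigma_rank = 20) {
  n <- nrow(knn$index)
  k <- ncol(knn$index)
  r <- min(sigma_rank, k)
  sigma <- knn$dist[, r]
  if (any(sigma == 0)) {
    # coincident points: fall back to the smallest positive neighbour distance
    for (j in which(sigma == 0)) {
      pos <- knn$dist[j, knn$dist[j, ] > 0]
      if (length(pos) == 0) {
        stop("niche ", j, " has all member distances zero; cannot set sigma",
             call. = FALSE)
      }
      sigma[j] <- min(pos)
    }
  }
  # members of niche j: anchor j (d = 0) and its k nearest neighbours
  i_idx <- c(seq_len(n), as.vector(knn$index))
  j_idx <- c(seq_len(n), rep(seq_len(n), times = k))
  d     <- c(rep(0, n), as.vector(knn$dist))
  w     <- exp(-(d^2) / (sigma[j_idx]^2))
  W <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = w, dims = c(n, n))
  list(W = W, sigma = sigma)
}

#' Niche cell-type composition vectors
#'
#' \eqn{v_{jm} = \sum_i w_{ij} I_{im} / \sum_i w_{ij}} where \eqn{I_{im}}
#' indicates that cell \eqn{i} has type \eqn{m}. Rows sum to 1.
#'
#' @param W sparse cells x niches weight matrix from [cell_niche_weights()].
#' @param cell_types factor of cell types (length = number of cells); its
#'   levels define the shared column order.
#' @return dense niches x types row-stochastic matrix.
#' @export
composition_vectors <- function(W, cell_types) {
  stopifnot(is.factor(cell_types), nrow(W) == length(cell_types))
  ind <- Matrix::sparseMatrix(i = seq_along(cell_types),
                              j = as.integer(cell_types), x = 1,
                              dims = c(length(cell_types),
                                       nlevels(cell_types)))
  num <- Matrix::t(W) %*% ind
  tot <- Matrix::rowSums(num)
  if (any(tot <= 0)) stop("niche with zero total weight", call. = FALSE)
  V <- as.matrix(num / tot)
  colnames(V) <- levels(cell_types)
  V
}

#' Symmetric degree normalization of an adjacency matrix
#'
#' \eqn{\tilde A = D^{-1/2} A D^{-1/2}} with \eqn{D} the diagonal degree
#' matrix. Isolated nodes get zero rows/columns (a self-loop is added
#' downstream as \eqn{\tilde A + I}).
#'
#' @param A symmetric nonnegative (sparse) adjacency.
#' @return sparse symmetric normalized adjacency with largest eigenvalue
#'   at most 1.
#' @export
normalize_adjacency <- function(A) {
  deg <- Matrix::rowSums(A)
  inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  Matrix::Diagonal(x = inv_sqrt) %*% A %*% Matrix::Diagonal(x = inv_sqrt)
}

#' Build per-sample niche graphs from a cell table
#'
#' For each sample: mutual-kNN adjacency between anchoring cells, Gaussian
#' cell-niche weights, cell-type composition vectors and the normalized
#' adjacency. Niches never cross samples; the cell-type alphabet (sorted
#' unique types) is shared across samples so composition columns align.
#'
#' @param cells data.frame with columns \code{Cell_ID, Sample, Cell_Type,
#'   x, y} (optional \code{z}); see [read_cell_table()].
#' @param k niche size: number of nearest neighbours around each anchoring
#'   cell (default 50).
#' @param sigma_rank neighbour rank for the Gaussian bandwidth
#'   \eqn{\sigma_j} (default 20).
#' @return object of class \code{niche_network}: list of per-sample graphs,
#'   each with \code{A} (binary adjacency), \code{A_norm}, \code{W},
#'   \code{V}, \code{sigma}, \code{cell_id}, \code{cell_type}; plus
#'   attribute \code{types} (shared level order).
#' @export
build_niche_network <- function(cells, k = 50, sigma_rank = 20) {
  cells <- validate_cell_table(cells)
  types <- sort(unique(as.character(cells$Cell_Type)))
  if (length(types) < 2) {
    stop("need at least 2 distinct cell types", call. = FALSE)
  }
  coord_cols <- intersect(c("x", "y", "z"), names(cells))
  graphs <- lapply(split(cells, cells$Sample, drop = TRUE), function(cs) {
    knn <- build_knn(as.matrix(cs[, coord_cols]), k = k)
    A <- build_niche_adjacency(knn)
    wl <- cell_niche_weights(knn, sigma_rank = sigma_rank)
    ct <- factor(as.character(cs$Cell_Type), levels = types)
    V <- composition_vectors(wl$W, ct)
    list(A = A, A_norm = normalize_adjacency(A), W = wl$W, V = V,
         sigma = wl$sigma, cell_id = cs$Cell_ID, cell_type = ct,
         sample = cs$Sample[1])
  })
  structure(graphs, class = "niche_network", types = types)
}

#' @export
print.niche_network <- function(x, ...) {
  cat(sprintf("Niche network: %d sample(s), %d cell types\n",
              length(x), length(attr(x, "types"))))
  for (g in x) {
    cat(sprintf("  %s: %d niches, %d edges\n", g$sample, nrow(g$V),
                Matrix::nnzero(g$A) / 2))
  }
  invisible(x)
}
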
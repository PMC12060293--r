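# Scaled exponential linear unit and its derivative.
SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA  <- 1.6732632423543772

selu <- function(x) {
  SELU_LAMBDA * ifelse(x > 0, x, SELU_ALPHA * (exp(x) - 1))
}

selu_grad <- function(x) {
  SELU_LAMBDA * ifelse(x > 0, 1, SELU_ALPHA * exp(x))
}

#' Initialise the graph pooling model
#'
#' A two-layer graph convolutional encoder (input M -> hidden -> hidden)
#' followed by a linear softmax cluster-assignment head (hidden -> K).
#' Weights are drawn from a seeded normal scaled by \code{1/sqrt(fan-in)}.
#'
#' @param n_types number of cell types M (input dimension).
#' @param hidden embedding dimension of both GCN layers (default 4).
#' @param n_clusters number of niche clusters K (default 6).
#' @param beta softmax scale of the assignment head (default 0.03).
#' @param seed RNG seed for the initial weights.
#' @return object of class \code{pooling_model} with weight matrices
#'   \code{W1}, \code{W2}, \code{WC}.
#' @export
init_pooling_model <- function(n_types, hidden = 4, n_clusters = 6,
                               beta = 0.03, seed = 0) {
  stopifnot(hidden >= 1, n_clusters >= 2, beta > 0)
  set.seed(seed)
  rw <- function(nin, nout) {
    matrix(stats::rnorm(nin * nout, sd = 1 / sqrt(nin)), nin, nout)
  }
  structure(list(W1 = rw(n_types, hidden),
                 W2 = rw(hidden, hidden),
                 WC = rw(hidden, n_clusters),
                 beta = beta, hidden = hidden, K = n_clusters),
            class = "pooling_model")
}

#' Two-layer GCN forward pass
#'
#' \eqn{X_t = SeLU((\tilde A + I) X_{t-1} W_t)} applied twice, with
#' \eqn{X_0} the niche composition matrix.
#'
#' @param V niches x types composition matrix.
#' @param A_norm symmetric normalized adjacency (see
#'   [normalize_adjacency()]).
#' @param model a \code{pooling_model}.
#' @return N x hidden embedding matrix \eqn{X_2}.
#' @export
gcn_forward <- function(V, A_norm, model) {
  fw <- pooling_forward(V, A_norm + Matrix::Diagonal(nrow(V)), model)
  fw$X2
}

#' Soft cluster assignment
#'
#' \eqn{C = softmax(\beta X_2 W_C)}, row-stochastic.
#'
#' @param X2 embedding matrix from [gcn_forward()].
#' @param model a \code{pooling_model}.
#' @return N x K row-stochastic assignment matrix.
#' @export
cluster_assign <- function(X2, model) {
  softmax_rows(model$beta * (as.matrix(X2) %*% model$WC))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# full forward pass with intermediates cached for backprop;
# S = A_norm + I (self-loops)
pooling_forward <- function(V, S, model) {
  P1 <- as.matrix(S %*% V)
  H1 <- P1 %*% model$W1
  X1 <- selu(H1)
  P2 <- as.matrix(S %*% X1)
  H2 <- P2 %*% model$W2
  X2 <- selu(H2)
  Z <- model$beta * (X2 %*% model$WC)
  C <- softmax_rows(Z)
  list(P1 = P1, H1 = H1, X1 = X1, P2 = P2, H2 = H2, X2 = X2, C = C)
}

#' Modularity loss
#'
#' \eqn{L_m = -Tr(C^T B C)/den} with modularity matrix
#' \eqn{B = A - d d^T/den} and \eqn{d} the degree vector. The default
#' denominator is the conventional \eqn{2m} (total edge weight), the form
#' used by Newman's modularity and by the DMoN graph-pooling objective;
#' \code{denominator = "nodes"} uses \eqn{2N} instead.
#'
#' @param C row-stochastic assignment matrix.
#' @param A symmetric (sparse) adjacency.
#' @param denominator \code{"edges"} (\eqn{2m}, default) or \code{"nodes"}
#'   (\eqn{2N}).
#' @return scalar loss (negative modularity).
#' @export
modularity_loss <- function(C, A, denominator = c("edges", "nodes")) {
  denominator <- match.arg(denominator)
  C <- as.matrix(C)
  d <- Matrix::rowSums(A)
  den <- if (denominator == "nodes") 2 * nrow(C) else sum(d)
  dTC <- drop(crossprod(d, C))
  tr <- sum(C * as.matrix(A %*% C)) - sum(dTC^2) / den
  -tr / den
}

#' Purity loss
#'
#' Mean squared deviation of niche compositions from their soft cluster
#' means: \eqn{L_p = \frac{1}{NM}\sum_j\sum_m (v_{jm} - \sum_k c_{jk}
#' v^*_{km})^2}, where \eqn{v^*_k} is the assignment-weighted mean
#' composition of cluster \eqn{k}.
#'
#' @param C row-stochastic assignment matrix (N x K).
#' @param V composition matrix (N x M).
#' @return scalar loss.
#' @export
purity_loss <- function(C, V) {
  C <- as.matrix(C); V <- as.matrix(V)
  R <- V - C %*% cluster_means(C, V)
  sum(R^2) / (nrow(V) * ncol(V))
}

# soft cluster mean compositions; empty clusters contribute zero rows
cluster_means <- function(C, V, eps = 1e-12) {
  nk <- colSums(C)
  Vs <- crossprod(C, V)
  Vs[nk > eps, ] <- Vs[nk > eps, , drop = FALSE] / nk[nk > eps]
  Vs[nk <= eps, ] <- 0
  Vs
}

#' Cluster-collapse regularization
#'
#' Penalises uneven cluster sizes:
#' \eqn{L_r = \frac{\sqrt K}{N(\sqrt K - 1)} \lVert (\sum_j c_{jk})_k
#' \rVert_2}. Ranges from \eqn{1/(\sqrt K - 1)} (perfectly balanced) to
#' \eqn{\sqrt K/(\sqrt K - 1)} (all niches in one cluster).
#'
#' @param C row-stochastic assignment matrix.
#' @return scalar loss.
#' @export
collapse_regularization <- function(C) {
  C <- as.matrix(C)
  K <- ncol(C); N <- nrow(C)
  sqrt(K) / (N * (sqrt(K) - 1)) * sqrt(sum(colSums(C)^2))
}

# loss + analytic gradients w.r.t. C for one (possibly block-diagonal) graph
pooling_loss_and_gradC <- function(C, A, V, lambda_m, lambda_p, lambda_r,
                                   denominator = "edges", eps = 1e-12) {
  N <- nrow(C); M <- ncol(V); K <- ncol(C)
  d <- Matrix::rowSums(A)
  den <- if (denominator == "nodes") 2 * N else sum(d)

  AC <- as.matrix(A %*% C)
  dTC <- drop(crossprod(d, C))
  Lm <- -(sum(C * AC) - sum(dTC^2) / den) / den
  Gm <- -(2 / den) * (AC - outer(d, dTC) / den)

  nk <- colSums(C)
  Vs <- cluster_means(C, V, eps)
  R <- V - C %*% Vs
  Lp <- sum(R^2) / (N * M)
  Gp1 <- -(2 / (N * M)) * R %*% t(Vs)
  Gstar <- -(2 / (N * M)) * crossprod(C, R)
  q <- rowSums(Vs * Gstar)
  inv_nk <- ifelse(nk > eps, 1 / nk, 0)
  Gp2 <- (V %*% t(Gstar) - matrix(q, N, K, byrow = TRUE)) *
    matrix(inv_nk, N, K, byrow = TRUE)
  Gp <- Gp1 + Gp2

  c0 <- sqrt(K) / (N * (sqrt(K) - 1))
  s <- sqrt(sum(nk^2))
  Lr <- c0 * s
  Gr <- matrix(c0 * nk / s, N, K, byrow = TRUE)

  list(loss = lambda_m * Lm + lambda_p * Lp + lambda_r * Lr,
       Lm = Lm, Lp = Lp, Lr = Lr,
       gradC = lambda_m * Gm + lambda_p * Gp + lambda_r * Gr)
}

# backprop from dL/dC to weight gradients
pooling_backward <- function(fw, S, model, gradC) {
  dZ <- fw$C * (gradC - rowSums(gradC * fw$C))
  dWC <- model$beta * crossprod(fw$X2, dZ)
  dX2 <- model$beta * dZ %*% t(model$WC)
  dH2 <- dX2 * selu_grad(fw$H2)
  dW2 <- crossprod(fw$P2, dH2)
  dX1 <- as.matrix(S %*% (dH2 %*% t(model$W2)))
  dH1 <- dX1 * selu_grad(fw$H1)
  dW1 <- crossprod(fw$P1, dH1)
  list(W1 = dW1, W2 = dW2, WC = dWC)
}
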
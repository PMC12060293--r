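test_that("GCN forward matches an independent dense-matrix evaluation", {
  set.seed(21)
  g <- random_niche_graph(n = 10, M = 5, k = 3)
  model <- init_pooling_model(5, hidden = 3, n_clusters = 4, seed = 1)
  X2 <- gcn_forward(g$V, g$A_norm, model)
  # independent evaluation with base-R dense algebra
  selu_ref <- function(x) {
    l <- 1.0507009873554805; a <- 1.6732632423543772
    ifelse(x > 0, l * x, l * a * (exp(x) - 1))
  }
  Sd <- as.matrix(g$A_norm) + diag(10)
  want <- selu_ref(Sd %*% selu_ref(Sd %*% g$V %*% model$W1) %*% model$W2)
  expect_equal(as.matrix(X2), want, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("GCN respects isolated nodes and node-permutation symmetry", {
  selu_ref <- function(x) {
    l <- 1.0507009873554805; a <- 1.6732632423543772
    ifelse(x > 0, l * x, l * a * (exp(x) - 1))
  }
  model <- init_pooling_model(3, hidden = 3, n_clusters = 2, seed = 2)
  model$W1 <- diag(3); model$W2 <- diag(3)
  V <- diag(3)[c(1, 2, 3, 1), ]
  A0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(4, 4))
  # no edges + identity weights: each node sees only itself
  expect_equal(as.matrix(gcn_forward(V, A0, model)), selu_ref(selu_ref(V)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # identical inputs on a degree-regular (cycle) graph: all rows equal
  n <- 8
  Ac <- Matrix::sparseMatrix(i = c(seq_len(n), seq_len(n)),
                             j = c(seq_len(n) %% n + 1,
                                   (seq_len(n) - 2) %% n + 1),
                             x = 1, dims = c(n, n))
  Veq <- matrix(rep(c(0.5, 0.3, 0.2), each = n), n, 3)
  X2 <- as.matrix(gcn_forward(Veq, normalize_adjacency(Ac), model))
  expect_equal(X2, X2[rep(1, n), ], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("cluster assignment softmax behaves at its limits", {
  model <- init_pooling_model(4, hidden = 3, n_clusters = 5, seed = 5)
  X2 <- matrix(0, 7, 3)
  C <- cluster_assign(X2, model)        # all-zero logits -> uniform rows
  expect_equal(C, matrix(1 / 5, 7, 5), tolerance = 1e-12)
  # one dominant logit -> near one-hot
  model$WC <- matrix(0, 3, 5); model$WC[1, 2] <- 1
  X2 <- matrix(c(1e4, 0, 0), 1, 3)
  C <- cluster_assign(X2, model)
  expect_equal(as.vector(C), c(0, 1, 0, 0, 0), tolerance = 1e-10)
  set.seed(6)
  C <- cluster_assign(matrix(rnorm(30), 10, 3), model)
  expect_equal(rowSums(C), rep(1, 10), tolerance = 1e-9)
})

test_that("loss terms match direct-summation oracles", {
  set.seed(31)
  for (rep in 1:5) {
    g <- random_niche_graph(n = 12, M = 4, k = 3)
    C <- random_stochastic(12, 3)
    for (den in c("edges", "nodes")) {
      expect_equal(modularity_loss(C, g$A, den),
                   oracle_modularity(C, g$A, den), tolerance = 1e-8)
    }
    expect_equal(purity_loss(C, g$V), oracle_purity(C, g$V),
                 tolerance = 1e-8)
    expect_equal(collapse_regularization(C), oracle_collapse(C),
                 tolerance = 1e-8)
  }
})

test_that("loss closed forms: uniform, balanced and collapsed assignments", {
  set.seed(32)
  g <- random_niche_graph(n = 14, M = 3, k = 4)
  A <- as.matrix(g$A); n <- nrow(A); K <- 4
  d <- rowSums(A)
  # uniform C: Tr(C'BC) = sum(B)/K
  Cu <- matrix(1 / K, n, K)
  for (den_name in c("edges", "nodes")) {
    den <- if (den_name == "nodes") 2 * n else sum(d)
    B <- A - outer(d, d) / den
    expect_equal(modularity_loss(Cu, g$A, den_name), -sum(B) / (K * den),
                 tolerance = 1e-12)
  }
  # identical compositions: purity loss is exactly zero
  Vsame <- matrix(rep(c(0.2, 0.3, 0.5), each = n), n, 3)
  expect_equal(purity_loss(random_stochastic(n, K), Vsame), 0,
               tolerance = 1e-12)
  # hard C matching two composition-homogeneous groups: zero purity
  Vtwo <- rbind(matrix(rep(c(1, 0, 0), each = 7), 7, 3),
                matrix(rep(c(0, 1, 0), each = 7), 7, 3))
  Chard <- cbind(rep(c(1, 0), c(7, 7)), rep(c(0, 1), c(7, 7)))
  expect_equal(purity_loss(Chard, Vtwo), 0, tolerance = 1e-12)
  # collapse term: balanced = 1/(sqrt(K)-1), collapsed = sqrt(K)/(sqrt(K)-1)
  expect_equal(collapse_regularization(matrix(1 / K, n, K)),
               1 / (sqrt(K) - 1), tolerance = 1e-12)
  Ccol <- matrix(0, n, K); Ccol[, 2] <- 1
  expect_equal(collapse_regularization(Ccol), sqrt(K) / (sqrt(K) - 1),
               tolerance = 1e-12)
})

test_that("modularity prefers the true split of two disconnected cliques", {
  block <- function(n) matrix(1, n, n) - diag(n)
  A <- Matrix::bdiag(block(5), block(5))
  Cgood <- cbind(rep(c(1, 0), c(5, 5)), rep(c(0, 1), c(5, 5)))
  Cswap <- cbind(rep(c(1, 0, 1, 0), c(3, 5, 2, 0)),
                 rep(c(0, 1, 0, 1), c(3, 5, 2, 0)))
  expect_lt(modularity_loss(Cgood, A), modularity_loss(Cswap, A))
  # K = 1 is constant: -sum(B)/den for the all-ones column
  C1 <- matrix(1, 10, 1)
  expect_equal(modularity_loss(C1, A), oracle_modularity(C1, A),
               tolerance = 1e-12)
})

test_that("analytic weight gradients agree with finite differences", {
  set.seed(41)
  g <- random_niche_graph(n = 10, M = 4, k = 3)
  model <- init_pooling_model(4, hidden = 3, n_clusters = 3, seed = 9)
  lossfun <- function(m) {
    fw <- nichetraj:::pooling_forward(g$V, g$S, m)
    nichetraj:::pooling_loss_and_gradC(fw$C, g$A, g$V, 0.3, 300, 0.1)$loss
  }
  fw <- nichetraj:::pooling_forward(g$V, g$S, model)
  lg <- nichetraj:::pooling_loss_and_gradC(fw$C, g$A, g$V, 0.3, 300, 0.1)
  gr <- nichetraj:::pooling_backward(fw, g$S, model, lg$gradC)
  h <- 1e-6
  for (p in c("W1", "W2", "WC")) {
    num <- model[[p]] * 0
    for (i in seq_along(num)) {
      mp <- model; mp[[p]][i] <- mp[[p]][i] + h
      mm <- model; mm[[p]][i] <- mm[[p]][i] - h
      num[i] <- (lossfun(mp) - lossfun(mm)) / (2 * h)
    }
    expect_equal(gr[[p]], num, tolerance = 1e-4)
  }
})

test_that("loss terms are permutation-equivariant", {
  set.seed(51)
  g <- random_niche_graph(n = 12, M = 4, k = 3)
  C <- random_stochastic(12, 4)
  pn <- sample(12); pk <- sample(4)
  A2 <- g$A[pn, pn]; C2 <- C[pn, pk]; V2 <- g$V[pn, ]
  expect_equal(modularity_loss(C, g$A), modularity_loss(C2, A2),
               tolerance = 1e-12)
  expect_equal(purity_loss(C, g$V), purity_loss(C2, V2), tolerance = 1e-12)
  expect_equal(collapse_regularization(C), collapse_regularization(C2),
               tolerance = 1e-12)
})
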
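#' Training configuration for the graph pooling model
#'
#' Defaults follow the method's published settings: loss weights
#' \eqn{\lambda_m = 0.3}, \eqn{\lambda_p = 300}, \eqn{\lambda_r = 0.1},
#' Adam with learning rate 0.03, at most 1000 epochs.
#'
#' @param lambda_m modularity loss weight.
#' @param lambda_p purity loss weight.
#' @param lambda_r collapse-regularization weight.
#' @param learning_rate Adam learning rate.
#' @param max_epochs maximum training epochs.
#' @param batch_size samples (graphs) per optimizer step; \code{NULL}
#'   processes all samples as a single block-diagonal graph.
#' @param modularity_denominator \code{"edges"} (default) or
#'   \code{"nodes"}; see [modularity_loss()].
#' @param seed seed for weight initialisation.
#' @return list of class \code{training_config}.
#' @export
training_config <- function(lambda_m = 0.3, lambda_p = 300, lambda_r = 0.1,
                            learning_rate = 0.03, max_epochs = 1000,
                            batch_size = NULL,
                            modularity_denominator = c("edges", "nodes"),
                            seed = 0) {
  stopifnot(lambda_m >= 0, lambda_p >= 0, lambda_r >= 0, max_epochs >= 1,
            learning_rate > 0)
  structure(list(lambda_m = lambda_m, lambda_p = lambda_p,
                 lambda_r = lambda_r, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = batch_size,
                 modularity_denominator = match.arg(modularity_denominator),
                 seed = seed),
            class = "training_config")
}

# concatenate sample graphs into one block-diagonal graph
concat_graphs <- function(graphs) {
  A <- do.call(Matrix::bdiag, lapply(graphs, `[[`, "A"))
  S <- do.call(Matrix::bdiag, lapply(graphs, function(g)
    g$A_norm + Matrix::Diagonal(nrow(g$V))))
  V <- do.call(rbind, lapply(graphs, `[[`, "V"))
  list(A = A, S = S, V = V,
       sizes = vapply(graphs, function(g) nrow(g$V), integer(1)))
}

#' Train the graph pooling model on one or more niche graphs
#'
#' Minimises \eqn{\lambda_m L_m + \lambda_p L_p + \lambda_r L_r} with Adam.
#' A batch is a set of sample graphs processed as one block-diagonal graph;
#' losses are normalized by the niches in the batch and summed over batches
#' per epoch. Training is deterministic for a fixed seed (batch order is
#' fixed, no stochastic layers).
#'
#' @param network a \code{niche_network} (see [build_niche_network()]).
#' @param n_clusters number of niche clusters K (default 6).
#' @param hidden GCN embedding dimension (default 4).
#' @param beta softmax scale (default 0.03).
#' @param config a [training_config()].
#' @param verbose print the loss every 100 epochs.
#' @return object of class \code{trained_pooling}: the fitted
#'   \code{pooling_model} plus per-epoch total loss (\code{history}) and
#'   the final per-term losses.
#' @export
train_pooling <- function(network, n_clusters = 6, hidden = 4, beta = 0.03,
                          config = training_config(), verbose = FALSE) {
  stopifnot(inherits(network, "niche_network"), length(network) >= 1)
  types <- attr(network, "types")
  model <- init_pooling_model(length(types), hidden = hidden,
                              n_clusters = n_clusters, beta = beta,
                              seed = config$seed)

  bs <- config$batch_size
  if (is.null(bs) || bs >= length(network)) bs <- length(network)
  batch_idx <- split(seq_along(network),
                     ceiling(seq_along(network) / bs))
  batches <- lapply(batch_idx, function(ix) concat_graphs(network[ix]))

  params <- c("W1", "W2", "WC")
  adam_m <- lapply(model[params], function(w) w * 0)
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  history <- numeric(config$max_epochs)
  final <- NULL

  for (epoch in seq_len(config$max_epochs)) {
    epoch_loss <- 0
    for (b in batches) {
      fw <- pooling_forward(b$V, b$S, model)
      lg <- pooling_loss_and_gradC(fw$C, b$A, b$V,
                                   config$lambda_m, config$lambda_p,
                                   config$lambda_r,
                                   config$modularity_denominator)
      if (!is.finite(lg$loss)) {
        stop(sprintf("non-finite loss at epoch %d (Lm=%g, Lp=%g, Lr=%g)",
                     epoch, lg$Lm, lg$Lp, lg$Lr), call. = FALSE)
      }
      grads <- pooling_backward(fw, b$S, model, lg$gradC)
      step <- step + 1L
      for (p in params) {
        adam_m[[p]] <- b1 * adam_m[[p]] + (1 - b1) * grads[[p]]
        adam_v[[p]] <- b2 * adam_v[[p]] + (1 - b2) * grads[[p]]^2
        mhat <- adam_m[[p]] / (1 - b1^step)
        vhat <- adam_v[[p]] / (1 - b2^step)
        model[[p]] <- model[[p]] -
          config$learning_rate * mhat / (sqrt(vhat) + eps)
      }
      epoch_loss <- epoch_loss + lg$loss
      final <- lg
    }
    history[epoch] <- epoch_loss
    if (verbose && (epoch %% 100 == 0 || epoch == 1)) {
      message(sprintf("epoch %4d  loss %.6f", epoch, epoch_loss))
    }
  }

  structure(list(model = model, history = history,
                 losses = c(total = final$loss, modularity = final$Lm,
                            purity = final$Lp, collapse = final$Lr),
                 types = types, config = config,
                 n_clusters = n_clusters, hidden = hidden, beta = beta),
            class = "trained_pooling")
}

#' @export
print.trained_pooling <- function(x, ...) {
  cat(sprintf("Trained pooling model: K = %d clusters, hidden = %d, %d epochs\n",
              x$n_clusters, x$hidden, length(x$history)))
  cat(sprintf("final losses: total %.5f (modularity %.5f, purity %.5f, collapse %.5f)\n",
              x$losses["total"], x$losses["modularity"],
              x$losses["purity"], x$losses["collapse"]))
  invisible(x)
}

#' Soft cluster assignments for every niche
#'
#' Runs the fitted encoder and assignment head on each sample graph.
#'
#' @param fit a \code{trained_pooling} object.
#' @param network the \code{niche_network} to assign (typically the one the
#'   model was trained on).
#' @return list of per-sample row-stochastic N x K matrices, in the order
#'   of \code{network}.
#' @export
assign_clusters <- function(fit, network) {
  stopifnot(inherits(fit, "trained_pooling"),
            inherits(network, "niche_network"))
  if (!identical(attr(network, "types"), fit$types)) {
    stop("cell-type alphabet of network does not match the fitted model",
         call. = FALSE)
  }
  lapply(network, function(g) {
    X2 <- gcn_forward(g$V, g$A_norm, fit$model)
    cluster_assign(X2, fit$model)
  })
}

#' Save / load a trained pooling model as JSON
#'
#' Plain-text serialization of the weight matrices and hyperparameters.
#'
#' @param fit a \code{trained_pooling} object.
#' @param path file path.
#' @return \code{save_pooling}: invisibly, \code{path};
#'   \code{load_pooling}: a \code{trained_pooling} object.
#' @export
save_pooling <- function(fit, path) {
  stopifnot(inherits(fit, "trained_pooling"))
  obj <- list(W1 = fit$model$W1, W2 = fit$model$W2, WC = fit$model$WC,
              beta = fit$beta, hidden = fit$hidden,
              n_clusters = fit$n_clusters, types = fit$types,
              losses = as.list(fit$losses))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_pooling
#' @export
load_pooling <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(list(W1 = as.matrix(obj$W1), W2 = as.matrix(obj$W2),
                          WC = as.matrix(obj$WC), beta = obj$beta,
                          hidden = obj$hidden, K = obj$n_clusters),
                     class = "pooling_model")
  structure(list(model = model, history = numeric(0),
                 losses = unlist(obj$losses), types = obj$types,
                 config = NULL, n_clusters = obj$n_clusters,
                 hidden = obj$hidden, beta = obj$beta),
            class = "trained_pooling")
}
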
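#' Spearman correlation between NT scores and a ground truth
#'
#' Because trajectory direction is arbitrary, the orientation-invariant
#' form returns the maximum over the two orientations \eqn{s} and
#' \eqn{1-s}, which equals \eqn{|\rho|}.
#'
#' @param cell_scores numeric vector of cell-level NT scores.
#' @param ground_truth numeric vector of the same length.
#' @param orientation_invariant return \eqn{\max(\rho(s), \rho(1-s))}
#'   (default \code{TRUE}).
#' @return Spearman coefficient, or \code{NA} with a warning when either
#'   vector is constant.
#' @export
spearman_vs_truth <- function(cell_scores, ground_truth,
                              orientation_invariant = TRUE) {
  stopifnot(length(cell_scores) == length(ground_truth),
            length(cell_scores) >= 3)
  if (stats::sd(cell_scores) == 0 || stats::sd(ground_truth) == 0) {
    warning("constant input vector: Spearman correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  rho <- stats::cor(cell_scores, ground_truth, method = "spearman")
  if (orientation_invariant) abs(rho) else rho
}

#' Cell-type density along the niche trajectory
#'
#' Gaussian kernel density of each cell type's NT scores on a fixed grid
#' over [0, 1]; every curve is renormalized to integrate to 1 on the grid.
#'
#' @param cell_scores numeric vector of cell-level NT scores.
#' @param cell_types character or factor of the same length.
#' @param bandwidth kernel bandwidth; default Scott's rule per type.
#' @param n_grid grid resolution (default 512).
#' @return long data.frame with columns \code{cell_type}, \code{nt},
#'   \code{density}.
#' @export
density_along_nt <- function(cell_scores, cell_types, bandwidth = NULL,
                             n_grid = 512) {
  stopifnot(length(cell_scores) == length(cell_types))
  grid <- seq(0, 1, length.out = n_grid)
  out <- lapply(split(cell_scores, as.character(cell_types)), function(s) {
    if (length(s) < 2 || stats::sd(s) == 0) {
      warning("cell type with < 2 distinct scores: delta-like density",
              call. = FALSE)
      bw <- 0.01
    } else {
      # Scott's rule for univariate data
      bw <- if (is.null(bandwidth)) stats::sd(s) * length(s)^(-1/5)
            else bandwidth
    }
    d <- vapply(grid, function(g) mean(stats::dnorm(g, mean = s, sd = bw)),
                numeric(1))
    area <- sum((d[-1] + d[-n_grid]) / 2) * (grid[2] - grid[1])
    d / area
  })
  data.frame(
    cell_type = rep(names(out), each = n_grid),
    nt = rep(grid, times = length(out)),
    density = unlist(out, use.names = FALSE),
    stringsAsFactors = FALSE)
}

#' Reproducibility of NT scores across runs
#'
#' Pairwise orientation-invariant Spearman correlations between the
#' cell-score vectors of repeated runs over the same cells.
#'
#' @param scores_runs list (length >= 2) of numeric vectors; if named,
#'   cell names must agree across runs.
#' @return symmetric matrix of pairwise \eqn{|\rho|} with unit diagonal.
#' @export
reproducibility <- function(scores_runs) {
  stopifnot(is.list(scores_runs), length(scores_runs) >= 2)
  n <- length(scores_runs[[1]])
  nm <- names(scores_runs[[1]])
  for (s in scores_runs) {
    if (length(s) != n ||
        (!is.null(nm) && !is.null(names(s)) && !identical(names(s), nm))) {
      stop("all runs must cover the same cells", call. = FALSE)
    }
  }
  R <- length(scores_runs)
  out <- diag(1, R)
  for (i in seq_len(R - 1)) {
    for (j in (i + 1):R) {
      out[i, j] <- out[j, i] <-
        spearman_vs_truth(scores_runs[[i]], scores_runs[[j]])
    }
  }
  out
}

#' Benchmark report against a known trajectory
#'
#' Convenience wrapper computing the overall and per-lineage
#' orientation-invariant Spearman correlation with a ground truth.
#'
#' @param cell_scores numeric vector of cell-level NT scores.
#' @param ground_truth numeric vector of true trajectory coordinates.
#' @param lineage optional per-cell lineage labels.
#' @return list with \code{spearman} and (if \code{lineage} given)
#'   \code{per_lineage_spearman}.
#' @export
evaluate_trajectory <- function(cell_scores, ground_truth, lineage = NULL) {
  rep <- list(spearman = spearman_vs_truth(cell_scores, ground_truth))
  if (!is.null(lineage)) {
    rep$per_lineage_spearman <- vapply(
      split(seq_along(lineage), lineage),
      function(ix) spearman_vs_truth(cell_scores[ix], ground_truth[ix]),
      numeric(1))
  }
  rep
}
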
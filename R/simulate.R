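#' Simulate benchmark spatial patterns with known trajectory ground truth
#'
#' Generates per-cell coordinates and cell-type labels laid out on one of
#' four spatial patterns, together with the true per-cell trajectory
#' coordinate. Each trajectory-bearing lineage draws a latent time
#' \eqn{t \sim U(0,1)} and maps it to space; cell types are assigned by
#' contiguous equal-width bins of the latent time, so the type sequence is
#' ordered along the trajectory. Non-trajectory lineages are placed uniformly
#' at random inside the bounding region.
#'
#' Patterns:
#' \describe{
#'   \item{\code{circular}}{Lineage-1 cells (types A-G) sit on circles of
#'     radius equal to their latent time, rescaled so the maximum radius is 1,
#'     at a uniformly random angle; lineage-2 cells (types H-J) are uniform in
#'     the unit disk. Ground truth is the radial distance of every cell.
#'     Default 1000 cells.}
#'   \item{\code{linear}}{Lineage-1 cells (types A-F) are spread along the
#'     x-axis in latent-time order inside a thin strip; lineage-2 (G-H) and
#'     lineage-3 (I-J) cells are uniform in the strip. Ground truth is the
#'     normalized x-position of the cell's projection onto the backbone.
#'     Default 500 cells.}
#'   \item{\code{quadratic}}{As \code{linear} but the backbone is the parabola
#'     \eqn{y = a x^2} on \eqn{x \in [-1, 1]}; ground truth is the normalized
#'     arc-length position of the orthogonal projection onto the curve.
#'     Default 500 cells.}
#'   \item{\code{disconnected}}{Two unrelated lineages with disjoint type
#'     sets (A-E, F-J) occupy mutually exclusive x-ranges (one central, one
#'     peripheral); x is proportional to latent time, y random. Ground truth
#'     is the rescaled x-position. Default 454 cells.}
#' }
#'
#' @param pattern one of \code{"circular"}, \code{"linear"},
#'   \code{"quadratic"}, \code{"disconnected"}.
#' @param n_cells total number of cells (>= 20). Defaults per pattern:
#'   1000, 500, 500, 454.
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @param sample_id value for the \code{Sample} column.
#' @param quad_a quadratic coefficient of the parabolic backbone.
#' @param lineage_prop optional numeric vector of lineage size proportions
#'   (length = number of lineages of the pattern). Defaults to the per-type
#'   counts implied by the equal-width type bins, e.g. 7:3 for
#'   \code{circular}.
#' @return an object of class \code{sim_niche_data}: a list with
#'   \code{cells} (data.frame \code{Cell_ID, Sample, Cell_Type, x, y}),
#'   \code{ground_truth} (numeric in [0,1], max exactly 1),
#'   \code{lineage} (integer lineage label per cell) and \code{pattern}.
#' @examples
#' sim <- simulate_niche_pattern("circular", seed = 1)
#' table(sim$cells$Cell_Type)
#' @export
simulate_niche_pattern <- function(pattern = c("circular", "linear",
                                               "quadratic", "disconnected"),
                                   n_cells = NULL, seed = NULL,
                                   sample_id = "sim", quad_a = 1,
                                   lineage_prop = NULL) {
  pattern <- match.arg(pattern)
  if (is.null(n_cells)) {
    n_cells <- switch(pattern, circular = 1000L, linear = 500L,
                      quadratic = 500L, disconnected = 454L)
  }
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 20L) {
    stop("'n_cells' must be a positive integer >= 20", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  n_lin <- switch(pattern, circular = 2L, linear = 3L, quadratic = 3L,
                  disconnected = 2L)
  if (!is.null(lineage_prop)) {
    if (length(lineage_prop) != n_lin || any(lineage_prop <= 0)) {
      stop(sprintf("'lineage_prop' must be %d positive proportions", n_lin),
           call. = FALSE)
    }
  }

  sim <- switch(pattern,
    circular     = sim_circular(n_cells, prop = lineage_prop),
    linear       = sim_backbone(n_cells, quadratic = FALSE, quad_a = quad_a,
                                prop = lineage_prop),
    quadratic    = sim_backbone(n_cells, quadratic = TRUE, quad_a = quad_a,
                                prop = lineage_prop),
    disconnected = sim_disconnected(n_cells, prop = lineage_prop))

  cells <- data.frame(
    Cell_ID   = sprintf("cell_%04d", seq_len(n_cells)),
    Sample    = sample_id,
    Cell_Type = sim$type,
    x         = sim$x,
    y         = sim$y,
    stringsAsFactors = FALSE)
  structure(list(cells = cells,
                 ground_truth = sim$truth,
                 lineage = sim$lineage,
                 pattern = pattern),
            class = "sim_niche_data")
}

#' @export
print.sim_niche_data <- function(x, ...) {
  cat(sprintf("Simulated spatial dataset: pattern '%s', %d cells, %d cell types\n",
              x$pattern, nrow(x$cells), length(unique(x$cells$Cell_Type))))
  cat(sprintf("ground truth in [%.3f, %.3f]\n",
              min(x$ground_truth), max(x$ground_truth)))
  invisible(x)
}

# split n into parts proportional to `prop`, exactly summing to n
# (largest-remainder rounding)
split_counts <- function(n, prop) {
  raw <- n * prop / sum(prop)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# contiguous equal-width bins of latent time -> type labels
bin_types <- function(t, types) {
  idx <- pmin(length(types), floor(t * length(types)) + 1L)
  types[idx]
}

sim_circular <- function(n, prop = NULL) {
  if (is.null(prop)) prop <- c(7, 3)          # 7 lineage-1 types, 3 lineage-2
  n_split <- split_counts(n, prop)
  n1 <- n_split[1]; n2 <- n_split[2]

  t1 <- stats::runif(n1)
  r1 <- t1 / max(t1)                          # rescale: max radius exactly 1
  th1 <- stats::runif(n1, 0, 2 * pi)
  type1 <- bin_types(t1, LETTERS[1:7])

  # uniform in unit disk; types H-J from an independent latent time
  r2 <- sqrt(stats::runif(n2))
  th2 <- stats::runif(n2, 0, 2 * pi)
  type2 <- bin_types(stats::runif(n2), LETTERS[8:10])

  list(x = c(r1 * cos(th1), r2 * cos(th2)),
       y = c(r1 * sin(th1), r2 * sin(th2)),
       type = c(type1, type2),
       truth = c(r1, r2),
       lineage = rep(1:2, c(n1, n2)))
}

# arc-length position in [0,1] of the orthogonal projection of (x, y)
# onto the parabola y = a u^2, u in [-1, 1] (fine-grid minimisation)
parabola_arcpos <- function(x, y, a, n_grid = 2001L) {
  u <- seq(-1, 1, length.out = n_grid)
  cu <- u^2 * a
  seg <- sqrt(diff(u)^2 + diff(cu)^2)
  arc <- c(0, cumsum(seg)); arc <- arc / arc[length(arc)]
  vapply(seq_along(x), function(i) {
    arc[which.min((u - x[i])^2 + (cu - y[i])^2)]
  }, numeric(1))
}

sim_backbone <- function(n, quadratic, quad_a, strip_height = 0.25,
                         prop = NULL) {
  if (is.null(prop)) prop <- c(6, 2, 2)       # types A-F / G-H / I-J
  n_split <- split_counts(n, prop)
  n1 <- n_split[1]; n2 <- n_split[2]; n3 <- n_split[3]

  t1 <- stats::runif(n1)
  t1 <- t1 / max(t1)                          # endpoint of backbone reached
  type1 <- bin_types(t1, LETTERS[1:6])

  if (!quadratic) {
    x1 <- t1
    y1 <- stats::runif(n1, 0, strip_height)
    xr <- stats::runif(n2 + n3, 0, 1)
    yr <- stats::runif(n2 + n3, 0, strip_height)
    truth_other <- xr                          # projection onto the x-axis
    truth1 <- x1
  } else {
    u1 <- 2 * t1 - 1                           # traverse parabola left->right
    x1 <- u1
    y1 <- quad_a * u1^2
    xr <- stats::runif(n2 + n3, -1, 1)
    yr <- stats::runif(n2 + n3, 0, quad_a)
    truth1 <- parabola_arcpos(x1, y1, quad_a)
    truth_other <- parabola_arcpos(xr, yr, quad_a)
  }
  type2 <- bin_types(stats::runif(n2), LETTERS[7:8])
  type3 <- bin_types(stats::runif(n3), LETTERS[9:10])

  truth <- c(truth1, truth_other)
  truth <- truth / max(truth)
  list(x = c(x1, xr), y = c(y1, yr),
       type = c(type1, type2, type3),
       truth = truth,
       lineage = rep(1:3, c(n1, n2, n3)))
}

sim_disconnected <- function(n, gap = c(0.45, 0.55), strip_height = 0.5,
                             prop = NULL) {
  if (is.null(prop)) prop <- c(5, 5)          # disjoint type sets A-E / F-J
  n_split <- split_counts(n, prop)
  n1 <- n_split[1]; n2 <- n_split[2]

  # lineage 1 central (small x ~ early time), lineage 2 peripheral:
  # mutually exclusive x-ranges separated by a gap
  t1 <- stats::runif(n1, 0, gap[1])
  t2 <- stats::runif(n2, gap[2], 1)
  t2 <- t2 / max(t2)                          # rescale so max x is exactly 1
  type1 <- bin_types(t1 / gap[1], LETTERS[1:5])
  type2 <- bin_types((t2 - gap[2]) / (1 - gap[2]), LETTERS[6:10])

  list(x = c(t1, t2),
       y = stats::runif(n, 0, strip_height),
       type = c(type1, type2),
       truth = c(t1, t2),
       lineage = rep(1:2, c(n1, n2)))
}

#' Write a simulated dataset to disk
#'
#' Writes \code{cells.csv} (header \code{Cell_ID,Sample,Cell_Type,x,y}) and
#' \code{ground_truth.csv} (header \code{Cell_ID,truth}) into \code{dir}.
#'
#' @param sim a \code{sim_niche_data} object.
#' @param dir output directory (created if absent).
#' @return invisibly, the two file paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_niche_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cells_path <- file.path(dir, "cells.csv")
  truth_path <- file.path(dir, "ground_truth.csv")
  utils::write.csv(sim$cells, cells_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(Cell_ID = sim$cells$Cell_ID,
                              truth = sim$ground_truth),
                   truth_path, row.names = FALSE, quote = FALSE)
  invisible(c(cells = cells_path, truth = truth_path))
}
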
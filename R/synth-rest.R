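#' Block-structured resting-state network specification
#'
#' Describes a node set partitioned into blocks with a compound
#' correlation structure: `within_block_r` between nodes of the same
#' block, `between_block_r` across blocks, unit variances. The implied
#' covariance matrix must be positive semi-definite.
#'
#' @param n_nodes number of nodes.
#' @param block_assignment integer block id per node; default two equal
#'   blocks.
#' @param within_block_r,between_block_r correlations, |r| < 1.
#' @param series_length number of time points.
#' @param seed integer RNG seed.
#' @return an object of class `network_spec` with the implied
#'   correlation matrix in `$sigma`.
#' @export
network_spec <- function(n_nodes, block_assignment = NULL,
                         within_block_r = 0.8, between_block_r = 0,
                         series_length = 150, seed = 1) {
  if (abs(within_block_r) >= 1 || abs(between_block_r) >= 1)
    stop_validation("correlations must satisfy |r| < 1 (got %g, %g)",
                    within_block_r, between_block_r)
  if (is.null(block_assignment))
    block_assignment <- rep(1:2, c(ceiling(n_nodes / 2), floor(n_nodes / 2)))
  if (length(block_assignment) != n_nodes)
    stop_validation("block_assignment must have one entry per node")
  same <- outer(block_assignment, block_assignment, "==")
  sigma <- ifelse(same, within_block_r, between_block_r)
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_validation(
      "within_block_r = %g, between_block_r = %g imply a non-PSD covariance (min eigenvalue %.3g)",
      within_block_r, between_block_r, min(ev))
  structure(list(n_nodes = as.integer(n_nodes),
                 block_assignment = as.integer(block_assignment),
                 within_block_r = within_block_r,
                 between_block_r = between_block_r,
                 series_length = as.integer(series_length),
                 seed = as.integer(seed), sigma = sigma),
            class = "network_spec")
}

#' Generate a synthetic resting-state node-by-time matrix
#'
#' Time points are i.i.d. draws from a multivariate normal with the
#' block correlation structure of the spec; the returned matrix has
#' nodes in rows. Reproducible given the spec's seed.
#'
#' @param spec a [network_spec()].
#' @return list with `series` (n_nodes x series_length matrix) and
#'   `blocks` (the ground-truth block labels).
#' @export
generate_restingstate <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(spec$seed)
  if (spec$n_nodes == 1L) {
    series <- matrix(stats::rnorm(spec$series_length), nrow = 1)
  } else {
    draws <- MASS::mvrnorm(spec$series_length,
                           mu = rep(0, spec$n_nodes), Sigma = spec$sigma)
    series <- t(draws)
  }
  rownames(series) <- sprintf("node_%03d", seq_len(spec$n_nodes))
  list(series = series, blocks = spec$block_assignment)
}
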
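#' Zero-phase band-pass filter for node time series
#'
#' Butterworth band-pass (default order 4) applied forward and backward
#' (`signal::filtfilt`) so the filter is zero-phase. Each series is
#' demeaned first; the DC component is rejected by construction.
#'
#' @param series numeric vector, or matrix with nodes in rows and time in
#'   columns, or a [node_series()].
#' @param fs sampling rate in Hz (taken from a `node_series`' `dt` when
#'   one is supplied).
#' @param low,high band edges in Hz; must satisfy
#'   `0 < low < high < fs/2`.
#' @param order Butterworth design order for each pass.
#' @return same shape as the input (a `node_series` stays one).
#' @export
bandpass <- function(series, fs = NULL, low = 0.01, high = 0.1, order = 4) {
  ns <- NULL
  if (inherits(series, "node_series")) {
    ns <- series
    series <- ns$series
    if (is.null(fs)) fs <- 1 / ns$dt
  }
  if (is.null(fs)) stop_validation("sampling rate fs is required")
  nyq <- fs / 2
  if (low <= 0 || high <= low || high >= nyq)
    stop_validation("band [%g, %g] Hz infeasible at fs = %g Hz (Nyquist %g)",
                    low, high, fs, nyq)
  filt <- signal::butter(order, c(low, high) / nyq, type = "pass")
  apply_one <- function(x) {
    signal::filtfilt(filt, x - mean(x))
  }
  if (is.matrix(series)) {
    out <- t(apply(series, 1, apply_one))
    dimnames(out) <- dimnames(series)
  } else {
    out <- apply_one(series)
  }
  if (!is.null(ns)) {
    ns$series <- out
    return(ns)
  }
  out
}

#' Nuisance regression of node time series
#'
#' Per node, ordinary least-squares residuals after projecting out the
#' supplied regressors plus an intercept. Collinear (rank-deficient)
#' columns are dropped with a warning.
#'
#' @param series matrix (nodes x time) or [node_series()].
#' @param regressors numeric matrix, time points in rows, one column per
#'   nuisance signal (motion parameters, WM/CSF means, outlier
#'   indicators...). `NULL` means intercept-only (demeaning).
#' @return residual series, same shape as input.
#' @export
nuisance_regress <- function(series, regressors = NULL) {
  ns <- NULL
  if (inherits(series, "node_series")) {
    ns <- series
    series <- ns$series
  }
  Y <- t(as.matrix(series))               # time x nodes
  X <- cbind(intercept = rep(1, nrow(Y)), regressors)
  if (nrow(X) != nrow(Y))
    stop_validation("regressors have %d rows but series %d time points",
                    nrow(X), nrow(Y))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    warning(sprintf("dropping %d collinear regressor column(s): %s",
                    ncol(X) - qx$rank,
                    paste(dropped, collapse = ", ")))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  res <- t(qr.resid(qx, Y))
  dimnames(res) <- dimnames(series)
  if (!is.null(ns)) {
    ns$series <- res
    return(ns)
  }
  res
}

#' Censor motion-corrupted time points with spike regressors
#'
#' One indicator regressor per flagged time point is regressed out
#' (together with an intercept), which zeroes the residual at the spike
#' while leaving clean time points consistent with simple deletion for
#' correlation purposes.
#'
#' @param series matrix (nodes x time) or [node_series()].
#' @param outlier_idx integer time indices (1-based) of motion spikes.
#' @return residual series with attribute `qc` (list with
#'   `n_censored`, `frac_censored`, `high_motion` flag when more than
#'   half the frames are censored).
#' @export
scrub_motion <- function(series, outlier_idx = integer()) {
  mat <- if (inherits(series, "node_series")) series$series else series
  nt <- ncol(mat)
  outlier_idx <- unique(as.integer(outlier_idx))
  if (length(outlier_idx) && (min(outlier_idx) < 1 || max(outlier_idx) > nt))
    stop_validation("outlier indices outside [1, %d]", nt)
  if (!length(outlier_idx)) {
    out <- series
    qc <- list(n_censored = 0L, frac_censored = 0, high_motion = FALSE)
  } else {
    spikes <- matrix(0, nrow = nt, ncol = length(outlier_idx))
    spikes[cbind(outlier_idx, seq_along(outlier_idx))] <- 1
    colnames(spikes) <- sprintf("spike_%d", outlier_idx)
    out <- nuisance_regress(series, spikes)
    frac <- length(outlier_idx) / nt
    qc <- list(n_censored = length(outlier_idx), frac_censored = frac,
               high_motion = frac > 0.5)
    if (qc$high_motion)
      warning(sprintf("%.0f%% of frames censored; subject flagged high-motion",
                      100 * frac))
  }
  attr(out, "qc") <- qc
  out
}

#' Pearson correlation matrix across node pairs
#'
#' All unordered node pairs; the matrix is symmetric with `NA` on the
#' diagonal (self-edges are excluded by convention). Zero-variance nodes
#' cannot be correlated: their edges are `NA` and they are listed in the
#' `qc` attribute.
#'
#' @param series matrix (nodes x time) or [node_series()].
#' @return node x node matrix with attributes `kind = "pearson_r"` and
#'   `qc`.
#' @export
pearson_matrix <- function(series) {
  mat <- if (inherits(series, "node_series")) series$series else as.matrix(series)
  if (nrow(mat) < 2) stop_validation("need >= 2 nodes for correlations")
  v <- apply(mat, 1, stats::var)
  flat <- which(v == 0)
  r <- suppressWarnings(stats::cor(t(mat)))
  if (length(flat)) {
    r[flat, ] <- NA_real_
    r[, flat] <- NA_real_
  }
  diag(r) <- NA_real_
  attr(r, "kind") <- "pearson_r"
  attr(r, "qc") <- list(zero_variance_nodes = flat)
  r
}

#' Fisher Z transform
#'
#' `Z = atanh(r)`, elementwise. Correlations at exactly +/-1 (possible
#' only in degenerate data) are clipped to `1 - 1e-7` in magnitude and
#' flagged in the `qc` attribute rather than mapping to infinity.
#'
#' @param r correlation value(s) / matrix from [pearson_matrix()].
#' @return same shape, `kind` attribute set to `"fisher_z"`.
#' @export
#' @examples
#' fisher_z(0.5)  # 0.5493
fisher_z <- function(r) {
  clipped <- which(abs(r) >= 1)
  if (length(clipped)) r[clipped] <- sign(r[clipped]) * (1 - 1e-7)
  z <- atanh(r)
  if (is.matrix(r)) {
    attr(z, "kind") <- "fisher_z"
    attr(z, "qc") <- list(n_clipped = length(clipped))
  }
  z
}

#' Group-level edge Z matrix from one-sample t-tests
#'
#' Per edge, the subjects' Fisher-Z values are tested against zero with
#' a one-sample t-test and the result expressed as a signed
#' standard-normal-equivalent Z (inverse-normal of the two-tailed p,
#' carrying the sign of the mean). Edges with zero across-subject
#' variance (all subjects identical) would be infinite; they are capped
#' at `cap` with a QC count.
#'
#' @param zmats list of subject Fisher-Z matrices (same dimensions).
#' @param cap magnitude cap for degenerate/huge Z values (default 8).
#' @return node x node matrix, `kind = "group_z"`, `NA` diagonal.
#' @export
group_edge_z <- function(zmats, cap = 8) {
  ns <- length(zmats)
  if (ns < 2) stop_validation("need >= 2 subjects for group edge statistics")
  d <- dim(zmats[[1]])
  arr <- array(unlist(zmats), dim = c(d, ns))
  m <- apply(arr, c(1, 2), mean)
  s <- apply(arr, c(1, 2), stats::sd)
  tt <- m / (s / sqrt(ns))
  p <- 2 * stats::pt(-abs(tt), df = ns - 1)
  z <- sign(m) * stats::qnorm(p / 2, lower.tail = FALSE)
  degen <- !is.na(s) & s == 0 & m != 0
  z[degen] <- sign(m[degen]) * cap
  z[!is.na(s) & s == 0 & m == 0] <- 0
  big <- is.finite(z) & abs(z) > cap
  z[big] <- sign(z[big]) * cap
  diag(z) <- NA_real_
  attr(z, "kind") <- "group_z"
  attr(z, "qc") <- list(n_capped = sum(degen, na.rm = TRUE))
  z
}

#' Threshold a Z matrix into a binary undirected adjacency
#'
#' `A[i, j] = 1` iff `|Z[i, j]| >= zcut` and `i != j`. The threshold is
#' inclusive; `NA` edges never pass.
#'
#' @param z symmetric Z matrix.
#' @param zcut threshold (default 2.3).
#' @return binary integer matrix with zero diagonal.
#' @export
threshold_matrix <- function(z, zcut = 2.3) {
  A <- ifelse(!is.na(z) & abs(z) >= zcut, 1L, 0L)
  diag(A) <- 0L
  A
}

#' Degree centrality of a binary adjacency matrix
#'
#' `CD[j]` is the number of suprathreshold edges incident to node j,
#' i.e. the row sum of the adjacency matrix.
#'
#' @param A binary symmetric adjacency with zero diagonal.
#' @param nodes optional node registry (data.frame with `name`).
#' @return data.frame with `node`, `degree`.
#' @export
degree_centrality <- function(A, nodes = NULL) {
  if (!isTRUE(all.equal(A, t(A)))) stop_validation("adjacency must be symmetric")
  deg <- as.integer(rowSums(A))
  nm <- if (!is.null(nodes)) nodes$name else
    if (!is.null(rownames(A))) rownames(A) else sprintf("node_%03d", seq_len(nrow(A)))
  data.frame(node = nm, degree = deg)
}

#' Cluster nodes by their connectivity profiles (mutual kNN)
#'
#' Node connectivity profiles (rows of the Z matrix, diagonal and `NA`s
#' treated as 0) are compared by Euclidean distance; two nodes are
#' joined when each is among the other's k nearest neighbors, and the
#' clusters are the connected components of that mutual-kNN graph.
#'
#' @param z node x node connectivity matrix.
#' @param k neighborhood size, must be < number of nodes.
#' @return integer cluster labels (1-based), one per node.
#' @export
knn_cluster <- function(z, k = 5) {
  n <- nrow(z)
  if (k >= n) stop_validation("k = %d must be smaller than n = %d nodes", k, n)
  prof <- z
  prof[is.na(prof)] <- 0
  d <- as.matrix(stats::dist(prof))
  diag(d) <- Inf
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    # neighbor set = everything within the k-th smallest distance, so
    # exact ties (e.g. identical profiles) are all included
    kth <- sort(d[i, ])[k]
    A[i, ] <- d[i, ] <= kth
  }
  mutual <- A & t(A)
  g <- igraph::graph_from_adjacency_matrix(mutual, mode = "undirected")
  as.integer(igraph::components(g)$membership)
}

#' Normality-gated paired comparison of degree centrality
#'
#' Paired over the nodes of a subregion: Shapiro-Wilk is run on the
#' paired differences; if its p exceeds 0.05 a paired t-test is used,
#' otherwise a Wilcoxon signed-rank test. All-zero differences short-cut
#' to "no difference" with p = 1.
#'
#' @param deg_a,deg_b numeric degree vectors over the same node set.
#' @param alpha normality gate level (default 0.05).
#' @return list with `branch` (`"paired_t"`, `"wilcoxon"` or `"none"`),
#'   `shapiro_p`, `statistic`, `p`.
#' @export
compare_degree <- function(deg_a, deg_b, alpha = 0.05) {
  if (length(deg_a) != length(deg_b))
    stop_validation("paired degree vectors differ in length")
  d <- deg_a - deg_b
  if (all(d == 0))
    return(list(branch = "none", shapiro_p = NA_real_,
                statistic = 0, p = 1))
  sw <- stats::shapiro.test(d)
  if (sw$p.value > alpha) {
    tt <- stats::t.test(deg_a, deg_b, paired = TRUE)
    list(branch = "paired_t", shapiro_p = sw$p.value,
         statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(deg_a, deg_b, paired = TRUE))
    list(branch = "wilcoxon", shapiro_p = sw$p.value,
         statistic = unname(wt$statistic), p = wt$p.value)
  }
}
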
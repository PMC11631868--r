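#' Voxel-wise BOLD percent-change map
#'
#' For each voxel, the mean signal over the response window is compared
#' against the mean over the baseline window:
#' `100 * (mean(response) - mean(baseline)) / mean(baseline)`.
#' Windows are 1-based inclusive acquisition index pairs. Voxels whose
#' baseline mean is zero cannot be expressed as a percent change; they
#' are returned as `NA`, counted in the `"qc"` attribute, and excluded
#' downstream.
#'
#' @param bold a [bold4d()] object.
#' @param baseline_window,response_window integer pairs, 1-based
#'   inclusive; baseline must end before the response begins.
#' @return a 3D numeric array of signed percent change with attribute
#'   `qc` (list with `n_invalid`).
#' @export
#' @examples
#' b <- bold4d(array(100, dim = c(2, 2, 1, 10)), tr = 6)
#' pc <- percent_change_map(b, c(1, 4), c(6, 10))
#' all(pc == 0)
percent_change_map <- function(bold, baseline_window = c(5, 45),
                               response_window = c(150, 200)) {
  stopifnot(inherits(bold, "bold4d"))
  d <- dim(bold$data)
  w <- check_windows(baseline_window, response_window, d[4])
  m <- matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])
  bm <- rowMeans(m[, w$baseline, drop = FALSE])
  rm_ <- rowMeans(m[, w$response, drop = FALSE])
  pct <- 100 * (rm_ - bm) / bm
  invalid <- bm == 0
  if (any(invalid)) {
    pct[invalid] <- NA_real_
    warning(sprintf("%d voxel(s) with zero baseline mean marked invalid",
                    sum(invalid)))
  }
  out <- array(pct, dim = d[1:3])
  attr(out, "qc") <- list(n_invalid = sum(invalid))
  out
}

#' Per-voxel Welch t-test of response vs baseline window
#'
#' Two-sample, two-tailed t-test with unequal ("heteroscedastic")
#' variances, vectorized across voxels. Degenerate conventions: if both
#' windows have zero variance, p = 1 when the means are equal and p = 0
#' when they differ.
#'
#' @inheritParams percent_change_map
#' @return a 3D array of p-values in [0, 1].
#' @export
voxel_ttest <- function(bold, baseline_window = c(5, 45),
                        response_window = c(150, 200)) {
  stopifnot(inherits(bold, "bold4d"))
  d <- dim(bold$data)
  w <- check_windows(baseline_window, response_window, d[4])
  if (length(w$baseline) < 2 || length(w$response) < 2)
    stop_validation("each window needs at least 2 acquisitions")
  m <- matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])
  p <- welch_p(m[, w$response, drop = FALSE], m[, w$baseline, drop = FALSE])
  array(p, dim = d[1:3])
}

# row-wise Welch two-tailed p, X and Y matrices of observations in columns
welch_p <- function(X, Y) {
  n1 <- ncol(X); n2 <- ncol(Y)
  m1 <- rowMeans(X); m2 <- rowMeans(Y)
  v1 <- rowSums((X - m1)^2) / (n1 - 1)
  v2 <- rowSums((Y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  degen <- se2 == 0
  if (any(degen)) p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  p
}

#' Ranked-p false-positive filter (step-up)
#'
#' Within a region of V voxels, p-values are ranked ascending and the
#' i-th smallest passes when `P(i) <= (i/V) * q * cV` for some admitted
#' rank. The rule is applied step-up: the largest rank i* satisfying the
#' inequality admits all voxels of rank <= i*; tied p-values share the
#' better (larger) rank; if no rank satisfies it, nothing passes. With
#' cV = 1 this is the Benjamini-Hochberg step-up procedure at level q
#' applied within the region.
#'
#' @param pvalues numeric vector of per-voxel p-values for one region.
#'   `NA` entries never pass and do not count toward V.
#' @param q false-positive filter rate in (0, 1].
#' @param cV predetermined constant, > 0.
#' @return logical vector, same length/order as `pvalues`.
#' @export
#' @examples
#' ranked_p_filter(c(0.01, 0.05, 0.10, 0.5, 0.9), q = 0.2) # 3 pass
ranked_p_filter <- function(pvalues, q = 0.2, cV = 1) {
  if (q <= 0 || q > 1) stop_validation("q must be in (0, 1]")
  if (cV <= 0) stop_validation("cV must be positive")
  pass <- rep(FALSE, length(pvalues))
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  V <- length(p)
  if (V == 0) return(pass)
  o <- order(p)
  thresh <- seq_len(V) / V * q * cV
  hit <- which(p[o] <= thresh)
  if (length(hit)) {
    k <- max(hit)
    sel <- logical(V)
    sel[o[seq_len(k)]] <- TRUE
    pass[ok] <- sel
  }
  pass
}

#' Classify voxels as positive / negative / null BOLD responses
#'
#' A voxel is `"positive"` when it both survived the ranked-p filter and
#' changed by at least `+threshold` percent, `"negative"` when it
#' survived and changed by at most `-threshold`; anything else
#' (sub-threshold, filtered out, or invalid/NA) is `"null"`. The
#' threshold is inclusive: |delta| exactly equal to the threshold
#' qualifies.
#'
#' @param pct 3D percent-change array from [percent_change_map()].
#' @param pass logical array of the same dimensions (filter survivors).
#' @param threshold magnitude threshold in percent (default 1).
#' @return character array (`"positive"`, `"negative"`, `"null"`).
#' @export
classify_voxels <- function(pct, pass, threshold = 1) {
  if (!identical(dim(pct), dim(pass)))
    stop_validation("percent-change map and pass flags have different dims")
  cls <- array("null", dim = dim(pct))
  ok <- pass & !is.na(pct)
  cls[ok & pct >= threshold] <- "positive"
  cls[ok & pct <= -threshold] <- "negative"
  cls
}

#' Per-region positive/negative voxel counts (volume of activation)
#'
#' @param classes character array from [classify_voxels()].
#' @param atlas an [atlas_labels()] object on the same grid.
#' @return data.frame with `region_id`, `region`, `n_negative`,
#'   `n_positive`, `n_voxels` (region size), one row per atlas region.
#' @export
region_voxel_counts <- function(classes, atlas) {
  stopifnot(inherits(atlas, "atlas_labels"))
  if (!identical(dim(classes), dim(atlas$labels)))
    stop_validation("class map grid %s does not match atlas grid %s",
                    paste(dim(classes), collapse = "x"),
                    paste(dim(atlas$labels), collapse = "x"))
  lab <- as.vector(atlas$labels)
  cls <- as.vector(classes)
  keep <- lab != 0L
  lab <- factor(lab[keep], levels = atlas$regions$id)
  cls <- cls[keep]
  data.frame(
    region_id = atlas$regions$id,
    region = atlas$regions$name,
    n_negative = as.integer(tapply(cls == "negative", lab, sum, default = 0)),
    n_positive = as.integer(tapply(cls == "positive", lab, sum, default = 0)),
    n_voxels = as.integer(tapply(rep(1L, length(lab)), lab, sum, default = 0)),
    row.names = NULL
  )
}

#' Run the voxel-level activation analysis for one subject
#'
#' Percent-change map, per-voxel Welch test, ranked-p filtering applied
#' within each atlas region, magnitude thresholding and per-region
#' counting, in one call.
#'
#' @param bold a [bold4d()].
#' @param atlas an [atlas_labels()] on the same grid.
#' @param config a [run_config()].
#' @return list with `pct` (array), `p` (array), `classes` (array) and
#'   `counts` (data.frame from [region_voxel_counts()]).
#' @export
subject_activation <- function(bold, atlas, config = run_config()) {
  pct <- percent_change_map(bold, config$baseline_window,
                            config$response_window)
  p <- voxel_ttest(bold, config$baseline_window, config$response_window)
  pass <- array(FALSE, dim = dim(p))
  lab <- atlas$labels
  for (rid in atlas$regions$id) {
    idx <- which(lab == rid)
    if (!length(idx)) next
    pv <- p[idx]
    pv[is.na(pct[idx])] <- NA   # invalid voxels never pass
    pass[idx] <- ranked_p_filter(pv, q = config$q, cV = config$cV)
  }
  classes <- classify_voxels(pct, pass, config$pct_threshold)
  list(pct = pct, p = p, classes = classes,
       counts = region_voxel_counts(classes, atlas))
}
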
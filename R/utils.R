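# internal validation helpers

stop_config <- function(...) {
  stop(structure(class = c("phmrikit_config_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

stop_validation <- function(...) {
  stop(structure(class = c("phmrikit_validation_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

#' Validate an acquisition-window pair
#'
#' Windows are 1-based inclusive acquisition index pairs, mirroring the
#' usual "acquisitions 150-200" phrasing; a window `c(5, 45)` therefore
#' spans 41 time points.
#'
#' @param baseline,response integer pairs (first, last), 1-based inclusive.
#' @param n_acquisitions total number of acquisitions available.
#' @return invisibly, a list with the expanded index vectors.
#' @keywords internal
check_windows <- function(baseline, response, n_acquisitions) {
  for (w in list(baseline = baseline, response = response)) {
    if (length(w) != 2L || any(!is.finite(w)) || w[1] > w[2])
      stop_validation("window must be an ordered index pair, got [%s]",
                      paste(w, collapse = ", "))
    if (w[1] < 1 || w[2] > n_acquisitions)
      stop_validation("window [%d, %d] outside acquisitions [1, %d]",
                      w[1], w[2], n_acquisitions)
  }
  if (baseline[2] >= response[1])
    stop_validation(
      "baseline window [%d, %d] must end before response window [%d, %d]",
      baseline[1], baseline[2], response[1], response[2])
  invisible(list(baseline = seq.int(baseline[1], baseline[2]),
                 response = seq.int(response[1], response[2])))
}

# sample that never surprises with length-1 x
sample_int <- function(x, size) x[sample.int(length(x), size)]
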
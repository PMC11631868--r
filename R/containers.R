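#' Per-subject 4D BOLD container
#'
#' Thin S3 wrapper around a 4D numeric array (x, y, z, acquisition) with
#' the acquisition metadata the analysis needs. Signal is in arbitrary
#' scanner units; all statistics downstream are relative (percent change).
#'
#' @param data numeric 4D array, dimensions x by y by z by acquisitions.
#' @param tr repetition time in seconds.
#' @param subject subject identifier.
#' @param group group label (e.g. dose).
#' @return an object of class `bold4d`.
#' @export
bold4d <- function(data, tr, subject = "s1", group = "vehicle") {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop_validation("bold4d data must be a 4D array")
  if (!all(is.finite(data)))
    stop_validation("bold4d series contain non-finite values")
  structure(list(data = data, tr = as.numeric(tr),
                 subject = as.character(subject),
                 group = as.character(group)),
            class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold4d> subject %s (group %s): %d x %d x %d grid, %d acquisitions, TR %gs\n",
              x$subject, x$group, d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' Atlas label volume with region lookup table
#'
#' @param labels integer 3D array; 0 is background, every nonzero value
#'   must appear in `regions$id`.
#' @param regions data.frame with columns `id`, `name` and optionally
#'   `hemisphere`.
#' @return an object of class `atlas_labels`.
#' @export
atlas_labels <- function(labels, regions) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop_validation("atlas labels must be a 3D array")
  labels <- array(as.integer(labels), dim = dim(labels))
  if (!all(c("id", "name") %in% names(regions)))
    stop_validation("region table needs columns 'id' and 'name'")
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  missing <- setdiff(present, regions$id)
  if (length(missing))
    stop_validation("labels present in volume but absent from region table: %s",
                    paste(missing, collapse = ", "))
  structure(list(labels = labels, regions = as.data.frame(regions)),
            class = "atlas_labels")
}

#' @export
print.atlas_labels <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<atlas_labels> %d x %d x %d volume, %d regions\n",
              d[1], d[2], d[3], nrow(x$regions)))
  invisible(x)
}

#' Region count of voxels for one atlas region
#' @param atlas an [atlas_labels()] object.
#' @param region_id integer region label.
#' @return number of voxels carrying that label.
#' @export
region_size <- function(atlas, region_id) {
  sum(atlas$labels == region_id)
}

#' Node-by-time series container for connectivity analysis
#'
#' @param series numeric matrix, nodes in rows, time points in columns.
#' @param nodes data.frame registry (`id`, `name`); defaults to row names
#'   or sequential ids.
#' @param dt sampling interval in seconds.
#' @param subject,group identifiers.
#' @return an object of class `node_series`.
#' @export
node_series <- function(series, nodes = NULL, dt = 1, subject = "s1",
                        group = "vehicle") {
  series <- as.matrix(series)
  if (any(!is.finite(series)))
    stop_validation("node series contain non-finite values")
  if (is.null(nodes)) {
    nm <- rownames(series)
    if (is.null(nm)) nm <- sprintf("node_%03d", seq_len(nrow(series)))
    nodes <- data.frame(id = seq_len(nrow(series)), name = nm)
  }
  if (nrow(nodes) != nrow(series))
    stop_validation("node registry (%d rows) does not match series (%d rows)",
                    nrow(nodes), nrow(series))
  structure(list(series = series, nodes = as.data.frame(nodes),
                 dt = as.numeric(dt), subject = as.character(subject),
                 group = as.character(group)),
            class = "node_series")
}

#' @export
print.node_series <- function(x, ...) {
  cat(sprintf("<node_series> subject %s (group %s): %d nodes x %d time points, dt %gs\n",
              x$subject, x$group, nrow(x$series), ncol(x$series), x$dt))
  invisible(x)
}
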
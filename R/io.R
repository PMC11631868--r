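#' Default run configuration
#'
#' Collects the tunable thresholds of the whole chain in one validated
#' list. Defaults are the standard settings of the awake-rodent
#' dose-response protocol this package implements: a 250-acquisition
#' session (TR 6 s) with baseline acquisitions 5-45 compared against the
#' post-injection response window 150-200 (both 1-based inclusive), a
#' ranked-p false-positive filter at q = 0.2 with c(V) = 1, a +/-1% BOLD
#' magnitude threshold, an edge threshold of |Z| = 2.3, a 0.01-0.1 Hz
#' band for resting-state series, alpha 0.05 with a 0.05-0.1 trend band,
#' and a minimum of 3 detectable samples per group for lipid analysis.
#'
#' @param ... named overrides for any default field.
#' @return a named list of class `phmri_config`.
#' @export
#' @examples
#' cfg <- run_config(q = 0.1)
#' cfg$q
run_config <- function(...) {
  cfg <- list(
    n_acquisitions = 250L,
    tr = 6,
    baseline_window = c(5L, 45L),
    response_window = c(150L, 200L),
    q = 0.2,
    cV = 1,
    pct_threshold = 1,
    zcut = 2.3,
    band = c(0.01, 0.1),
    filter_order = 4L,
    alpha = 0.05,
    trend_alpha = 0.1,
    n_required = 3L,
    knn_k = 5L,
    z_cap = 8,
    session_length = 600
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_config("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  with(cfg, {
    if (q <= 0 || q > 1) stop_config("q must be in (0, 1]")
    if (cV <= 0) stop_config("cV must be positive")
    if (pct_threshold < 0) stop_config("pct_threshold must be >= 0")
    if (band[1] <= 0 || band[2] <= band[1]) stop_config("invalid band")
    if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  })
  check_windows(cfg$baseline_window, cfg$response_window, cfg$n_acquisitions)
  class(cfg) <- c("phmri_config", "list")
  cfg
}

#' Read a NIfTI-1 volume as BOLD data or atlas labels
#'
#' Dispatches on dimensionality: 4D volumes load as [bold4d()], 3D
#' integer volumes as a bare label array (pair it with a region table via
#' [atlas_labels()]).
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param tr repetition time override in seconds; default taken from the
#'   header pixdim.
#' @param subject,group identifiers attached to 4D reads.
#' @return a [bold4d()] for 4D input, an integer 3D array for 3D input.
#' @export
read_nifti <- function(path, tr = NULL, subject = "s1", group = "vehicle") {
  if (!file.exists(path)) stop_validation("no such file: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L) {
    if (is.null(tr)) tr <- RNifti::pixdim(img)[4]
    bold4d(array(as.numeric(img), dim = d), tr = tr,
           subject = subject, group = group)
  } else if (length(d) == 3L) {
    array(as.integer(round(img)), dim = d)
  } else {
    stop_validation("expected a 3D or 4D NIfTI, got %d dimensions", length(d))
  }
}

#' Write a 3D/4D array or bold4d to NIfTI-1
#' @param x numeric array or [bold4d()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  if (inherits(x, "bold4d")) {
    img <- RNifti::asNifti(x$data)
    RNifti::pixdim(img) <- c(1, 1, 1, x$tr)
  } else {
    img <- RNifti::asNifti(x)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a CSV table against a schema
#'
#' @param path CSV file with a header row.
#' @param required character vector of required column names.
#' @param numeric character vector of columns that must parse as numeric;
#'   offending row numbers are reported.
#' @return a data.frame.
#' @export
read_table <- function(path, required = character(), numeric = character()) {
  if (!file.exists(path)) stop_validation("no such file: %s", path)
  if (file.size(path) == 0) stop_validation("empty input file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0 && length(required) && !all(required %in% names(df)))
    stop_validation("empty input table: %s", path)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_validation("%s: missing column(s): %s", path,
                    paste(missing, collapse = ", "))
  for (col in numeric) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad))
      stop_validation("%s: non-numeric '%s' at row(s) %s", path, col,
                      paste(utils::head(bad, 5), collapse = ", "))
    df[[col]] <- v
  }
  df
}

#' Write a table deterministically (columns as given, no row names)
#' @param df data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON provenance manifest for a run
#'
#' Records the configuration, the seed and a content hash of the
#' configuration so an output directory is traceable to its settings.
#'
#' @param path output .json path.
#' @param config a [run_config()] list.
#' @param seed integer seed used for the run.
#' @param extra optional named list folded into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, extra = list()) {
  cfg <- unclass(config)
  manifest <- c(list(
    package = "phmrikit",
    version = as.character(utils::packageVersion("phmrikit")),
    seed = as.integer(seed),
    config = cfg,
    config_hash = config_hash(cfg)
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# order-independent hash of the configuration list
config_hash <- function(cfg) {
  cfg <- cfg[order(names(cfg))]
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  # small polynomial rolling hash over the serialized bytes; avoids a
  # digest dependency and stays inside 31-bit integer arithmetic
  bytes <- as.integer(charToRaw(as.character(s)))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
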
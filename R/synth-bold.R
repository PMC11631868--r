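#' Scan design for a synthetic dose-response BOLD study
#'
#' Encodes the acquisition protocol the generators emulate: a
#' 250-acquisition session at TR 6 s, baseline acquisitions 5-45,
#' post-injection response window 150-200 (both 1-based inclusive), and
#' a four-group dose design. Default group sizes follow the usual
#' awake-imaging attrition pattern (4, 4, 6, 5 usable subjects for
#' vehicle, 3, 10 and 30 mg/kg).
#'
#' @param n_acquisitions total acquisitions per session.
#' @param tr repetition time in seconds.
#' @param baseline_window,response_window 1-based inclusive index pairs;
#'   must be disjoint with baseline first.
#' @param groups data.frame with `label`, `dose` (mg/kg), `n_subjects`
#'   (each >= 2).
#' @param seed integer RNG seed.
#' @return an object of class `bold_design`.
#' @export
bold_design <- function(n_acquisitions = 250, tr = 6,
                        baseline_window = c(5, 45),
                        response_window = c(150, 200),
                        groups = data.frame(
                          label = c("vehicle", "3mg", "10mg", "30mg"),
                          dose = c(0, 3, 10, 30),
                          n_subjects = c(4, 4, 6, 5)),
                        seed = 1) {
  check_windows(baseline_window, response_window, n_acquisitions)
  if (!all(c("label", "dose", "n_subjects") %in% names(groups)))
    stop_validation("groups needs columns label, dose, n_subjects")
  if (any(groups$n_subjects < 2))
    stop_validation("every group needs >= 2 subjects")
  structure(list(n_acquisitions = as.integer(n_acquisitions), tr = tr,
                 baseline_window = baseline_window,
                 response_window = response_window,
                 groups = groups, seed = as.integer(seed)),
            class = "bold_design")
}

#' Synthetic atlas label volume
#'
#' A small 3D label volume standing in for a full segmented brain
#' atlas: the inner volume (one-voxel background margin on every face)
#' is partitioned into `n_regions` equal slabs along x. Deterministic —
#' no randomness involved.
#'
#' @param dim integer grid dimensions (default 24 x 24 x 8).
#' @param n_regions number of regions (default 6).
#' @return an [atlas_labels()] object; region names are
#'   `region_01 ... region_NN` with alternating hemisphere tags.
#' @export
synth_atlas <- function(dim = c(24, 24, 8), n_regions = 6) {
  if (n_regions < 1 || n_regions > dim[1] - 2)
    stop_validation("n_regions must be in [1, %d] for this grid", dim[1] - 2)
  lab <- array(0L, dim = dim)
  inner_x <- 2:(dim[1] - 1)
  slab <- cut(seq_along(inner_x), breaks = n_regions, labels = FALSE)
  for (i in seq_along(inner_x))
    lab[inner_x[i], 2:(dim[2] - 1), 2:(dim[3] - 1)] <- slab[i]
  regions <- data.frame(id = seq_len(n_regions),
                        name = sprintf("region_%02d", seq_len(n_regions)),
                        hemisphere = rep(c("L", "R"),
                                         length.out = n_regions))
  atlas_labels(lab, regions)
}

#' Regional effect specification for the BOLD generator
#'
#' Describes the injected signal change of one atlas region: a signed
#' percent change per dose group (negative = deactivation) applied as a
#' step over the response window, carried by a fraction of the region's
#' voxels ("responders").
#'
#' @param region_id atlas label the effect lives in.
#' @param group_pct named numeric vector of mean percent change per
#'   group label; groups not named get 0.
#' @param responder_fraction fraction of region voxels carrying the
#'   effect, in [0, 1].
#' @return an object of class `region_effect_spec`.
#' @export
#' @examples
#' # the inverse dose-response pattern: strongest at the lowest dose
#' region_effect_spec(2, c(`3mg` = -3, `10mg` = -2.5, `30mg` = -1.5))
region_effect_spec <- function(region_id, group_pct,
                               responder_fraction = 1) {
  if (responder_fraction < 0 || responder_fraction > 1)
    stop_validation("responder_fraction must be in [0, 1]")
  if (is.null(names(group_pct)) || any(names(group_pct) == ""))
    stop_validation("group_pct must be a fully named vector")
  structure(list(region_id = as.integer(region_id),
                 group_pct = group_pct,
                 responder_fraction = responder_fraction),
            class = "region_effect_spec")
}

#' Generate synthetic 4D BOLD data with known regional effects
#'
#' Every voxel starts at a constant baseline level of 100 arbitrary
#' units (so percent change is numerically transparent). For each
#' effect, a per-subject random subset of the region's voxels
#' ("responders") is scaled by `1 + pct/100` over the response window —
#' a step effect, matching an analysis that compares window means.
#' I.i.d. Gaussian noise of SD `noise_sd` (in the same arbitrary units;
#' on a baseline of 100 this equals percent units) is added to every
#' sample. Bit-identical output for identical seed and specs.
#'
#' @param design a [bold_design()].
#' @param atlas an [atlas_labels()] (e.g. [synth_atlas()]).
#' @param effects list of [region_effect_spec()] objects.
#' @param noise_sd Gaussian noise SD in signal units (default 0 —
#'   noise-free).
#' @param baseline_level constant pre-injection signal level.
#' @return list with `subjects` (list of [bold4d()]), `truth`
#'   (data.frame: group, subject, region_id, pct, n_responders,
#'   n_voxels) and `design`.
#' @export
generate_bold <- function(design, atlas, effects = list(), noise_sd = 0,
                          baseline_level = 100) {
  stopifnot(inherits(design, "bold_design"), inherits(atlas, "atlas_labels"))
  for (e in effects) {
    if (!inherits(e, "region_effect_spec"))
      stop_config("effects must be region_effect_spec objects")
    if (!e$region_id %in% atlas$regions$id)
      stop_config("effect references unknown region id %d", e$region_id)
  }
  d3 <- dim(atlas$labels)
  nt <- design$n_acquisitions
  rw <- seq.int(design$response_window[1], design$response_window[2])
  set.seed(design$seed)
  subjects <- list()
  truth <- list()
  for (gi in seq_len(nrow(design$groups))) {
    glab <- design$groups$label[gi]
    for (si in seq_len(design$groups$n_subjects[gi])) {
      sid <- sprintf("%s_s%02d", glab, si)
      vol <- matrix(baseline_level, nrow = prod(d3), ncol = nt)
      for (e in effects) {
        pct <- if (glab %in% names(e$group_pct)) e$group_pct[[glab]] else 0
        vox <- which(atlas$labels == e$region_id)
        n_resp <- round(e$responder_fraction * length(vox))
        resp <- if (n_resp > 0) sort(sample_int(vox, n_resp)) else integer(0)
        if (length(resp) && pct != 0)
          vol[resp, rw] <- vol[resp, rw] * (1 + pct / 100)
        truth[[length(truth) + 1L]] <- data.frame(
          group = glab, subject = sid, region_id = e$region_id,
          pct = pct, n_responders = n_resp, n_voxels = length(vox))
      }
      if (noise_sd > 0)
        vol <- vol + matrix(stats::rnorm(length(vol), sd = noise_sd),
                            nrow = nrow(vol))
      subjects[[sid]] <- bold4d(array(vol, dim = c(d3, nt)), tr = design$tr,
                                subject = sid, group = glab)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(group = character(), subject = character(),
               region_id = integer(), pct = numeric(),
               n_responders = integer(), n_voxels = integer())
  rownames(truth) <- NULL
  list(subjects = subjects, truth = truth, design = design)
}
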
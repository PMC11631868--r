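#' Lipid effect specification for the table generator
#'
#' One lipid in one compartment, with a true group mean per dose group,
#' a within-group coefficient of variation, a below-detection
#' probability (left-censoring) and an outlier injection rate.
#'
#' @param lipid lipid name.
#' @param compartment `"plasma"` or one of the six CNS regions
#'   (`HYP`, `CER`, `STR`, `THAL`, `CTX`, `HIPP`).
#' @param group_means named non-negative numeric vector of true means
#'   (moles/g tissue or pmol/mL plasma) per group label.
#' @param cv coefficient of variation (fraction, >= 0).
#' @param p_below_detection probability a sample falls below the
#'   detection limit, in [0, 1].
#' @param outlier_rate probability a sample is replaced by an injected
#'   outlier, in [0, 1].
#' @return an object of class `lipid_effect_spec`.
#' @export
lipid_effect_spec <- function(lipid, compartment, group_means, cv = 0.3,
                              p_below_detection = 0, outlier_rate = 0) {
  if (any(group_means < 0)) stop_validation("group means must be >= 0")
  if (cv < 0) stop_validation("cv must be >= 0")
  for (p in c(p_below_detection, outlier_rate))
    if (p < 0 || p > 1) stop_validation("probabilities must be in [0, 1]")
  if (is.null(names(group_means)) || any(names(group_means) == ""))
    stop_validation("group_means must be a fully named vector")
  structure(list(lipid = lipid, compartment = compartment,
                 group_means = group_means, cv = cv,
                 p_below_detection = p_below_detection,
                 outlier_rate = outlier_rate),
            class = "lipid_effect_spec")
}

#' Generate a synthetic long-format lipid concentration table
#'
#' Concentrations are log-normal around each group's true mean with the
#' specified CV (exactly the mean when cv = 0). Below-detection draws
#' are flagged `detected = FALSE` with concentration 0 (left-censoring
#' at the instrument limit). Injected outliers replace a draw with a
#' value 3 sample-SDs above the mean of the group's other draws, i.e.
#' more than 2 SDs out relative to the uncontaminated group. Ground
#' truth (true means and true fold change of every group against the
#' vehicle group, where present) is returned alongside.
#'
#' @param specs list of [lipid_effect_spec()] objects.
#' @param n_per_group subjects per group (>= 2; the study convention is
#'   5).
#' @param seed integer RNG seed.
#' @param vehicle_label group label used as the fold-change reference.
#' @return list with `table` (subject, group, compartment, lipid,
#'   concentration, detected) and `truth` (lipid, compartment, group,
#'   true_mean, true_fold, true_direction).
#' @export
generate_lipid_table <- function(specs, n_per_group = 5, seed = 1,
                                 vehicle_label = "vehicle") {
  if (n_per_group < 2) stop_validation("n_per_group must be >= 2")
  for (s in specs)
    if (!inherits(s, "lipid_effect_spec"))
      stop_config("specs must be lipid_effect_spec objects")
  set.seed(seed)
  rows <- list(); truth <- list()
  for (s in specs) {
    for (g in names(s$group_means)) {
      m <- s$group_means[[g]]
      if (m == 0 || s$cv == 0) {
        vals <- rep(m, n_per_group)
      } else {
        s2 <- log(1 + s$cv^2)
        vals <- stats::rlnorm(n_per_group,
                              meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
      }
      if (s$outlier_rate > 0 && n_per_group >= 3) {
        hit <- which(stats::runif(n_per_group) < s$outlier_rate)
        for (i in hit) {
          others <- vals[-i]
          spread <- stats::sd(others)
          if (spread == 0) spread <- max(abs(mean(others)), 1) * 0.25
          vals[i] <- mean(others) + 3 * spread
        }
      }
      detected <- rep(m > 0, n_per_group)
      if (s$p_below_detection > 0) {
        bdl <- stats::runif(n_per_group) < s$p_below_detection
        detected[bdl] <- FALSE
      }
      vals[!detected] <- 0
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("%s_s%02d", g, seq_len(n_per_group)),
        group = g, compartment = s$compartment, lipid = s$lipid,
        concentration = vals, detected = detected)
      veh <- if (vehicle_label %in% names(s$group_means))
        s$group_means[[vehicle_label]] else NA_real_
      truth[[length(truth) + 1L]] <- data.frame(
        lipid = s$lipid, compartment = s$compartment, group = g,
        true_mean = m,
        true_fold = if (!is.na(veh) && veh > 0 && m > 0)
          max(m, veh) / min(m, veh) else NA_real_,
        true_direction = if (!is.na(veh) && veh > 0 && m > 0) {
          if (m >= veh) "increase" else "decrease"
        } else NA_character_)
    }
  }
  table <- do.call(rbind, rows); rownames(table) <- NULL
  truth <- do.call(rbind, truth); rownames(truth) <- NULL
  list(table = table, truth = truth)
}
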
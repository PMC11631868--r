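#' Default behavioral effect pattern for the generator
#'
#' Group means and SDs per measure for a four-dose open-field / novel
#' object / tail-flick battery, chosen to emulate the qualitative
#' pattern of an acute sedating high dose: a dose-dependent decrease in
#' distance traveled, the high dose trading wall time for corner time,
#' near-floor center time throughout, an above-chance investigation
#' ratio only in vehicle, and no treatment effect on tail-flick
#' latency. Units: distance m, times s (600 s session), IR
#' dimensionless, latency s.
#'
#' @return data.frame with `measure`, `group`, `mean`, `sd`.
#' @export
default_behavior_effects <- function() {
  grp <- c("vehicle", "3mg", "10mg", "30mg")
  rbind(
    data.frame(measure = "distance", group = grp,
               mean = c(25, 22, 20, 10), sd = 5),
    data.frame(measure = "wall_time", group = grp,
               mean = c(250, 150, 220, 39), sd = 60),
    data.frame(measure = "corner_time", group = grp,
               mean = c(120, 150, 130, 260), sd = 60),
    data.frame(measure = "center_time", group = grp,
               mean = c(5, 5, 5, 5), sd = 3),
    data.frame(measure = "ir", group = grp,
               mean = c(0.65, 0.52, 0.5, 0.48), sd = 0.1),
    data.frame(measure = "tail_flick", group = grp,
               mean = c(8, 8, 8, 8), sd = 1.5)
  )
}

#' Generate a synthetic long-format behavioral table
#'
#' Per-group normal draws for each measure of the effect pattern.
#' Times and distances are floored at 0, investigation ratios clamped
#' to [0, 1]. A zero SD is allowed (the draw is then the constant
#' mean) but only when explicitly requested in the pattern.
#'
#' @param effects data.frame with `measure`, `group`, `mean`, `sd`
#'   (default [default_behavior_effects()]).
#' @param n_per_group subjects per group (the study convention is 6).
#' @param seed integer RNG seed.
#' @return list with `table` (subject, group, measure, value) and
#'   `truth` (the effect pattern).
#' @export
generate_behavior_table <- function(effects = default_behavior_effects(),
                                    n_per_group = 6, seed = 1) {
  if (any(effects$sd < 0)) stop_validation("sd must be >= 0")
  set.seed(seed)
  rows <- lapply(seq_len(nrow(effects)), function(i) {
    e <- effects[i, ]
    v <- stats::rnorm(n_per_group, e$mean, e$sd)
    if (e$measure == "ir") v <- pmin(pmax(v, 0), 1) else v <- pmax(v, 0)
    data.frame(subject = sprintf("%s_s%02d", e$group, seq_len(n_per_group)),
               group = e$group, measure = e$measure, value = v)
  })
  table <- do.call(rbind, rows); rownames(table) <- NULL
  list(table = table, truth = effects)
}
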
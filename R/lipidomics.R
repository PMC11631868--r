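#' Single-pass 2-SD outlier exclusion within a group
#'
#' Mean and sample SD are computed once on all values (the candidate
#' included); any value farther than 2 SD from that mean is dropped.
#' There is no re-iteration. Groups of fewer than 3 values are returned
#' untouched with a QC note, and an all-equal group (SD 0) excludes
#' nothing — the rule is vacuous there.
#'
#' Note a structural property of the including-candidate rule: a single
#' point in a group of n can deviate by at most `(n-1)/sqrt(n)` sample
#' SDs, so exclusion of a lone outlier is only possible for n >= 6.
#'
#' @param values numeric concentrations of one group.
#' @return list with `values` (retained), `excluded` (dropped values),
#'   `note` (character, `""` when unremarkable).
#' @export
#' @examples
#' exclude_outliers(c(rep(0, 9), 100))$excluded  # 100 (2.85 SD out)
exclude_outliers <- function(values) {
  if (length(values) < 3)
    return(list(values = values, excluded = numeric(0),
                note = "n < 3: outlier rule not applied"))
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0)
    return(list(values = values, excluded = numeric(0), note = ""))
  keep <- abs(values - m) <= 2 * s
  list(values = values[keep], excluded = values[!keep], note = "")
}

#' Pooled-variance (equal-variance) two-sample t-test
#'
#' Two-tailed Student t with a pooled variance estimate — the
#' spreadsheet "type 2" convention. Degenerate conventions: with zero
#' pooled variance, p = 1 for equal means and p = 0 otherwise.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
#' @examples
#' two_sample_t(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, p ~ 0.288
two_sample_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2)
    stop_validation("each group needs >= 2 values (got %d, %d)", na, nb)
  ma <- mean(a); mb <- mean(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  df <- na + nb - 2
  if (sp2 == 0) {
    return(list(t = if (ma == mb) 0 else sign(ma - mb) * Inf, df = df,
                p = if (ma == mb) 1 else 0, mean_a = ma, mean_b = mb))
  }
  tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df),
       mean_a = ma, mean_b = mb)
}

#' CNS-combined lipid level per subject
#'
#' For one lipid, the concentrations measured in the six CNS
#' compartments are summed per subject so the subject count is
#' preserved; subjects missing any compartment are dropped with a QC
#' note. The two requested groups are then compared with the pooled
#' t-test.
#'
#' @param table long-format lipid table (see [generate_lipid_table()]):
#'   columns `subject`, `group`, `compartment`, `lipid`,
#'   `concentration`, `detected`.
#' @param lipid lipid name to combine.
#' @param group_a,group_b group labels to compare (e.g. treated vs
#'   vehicle).
#' @param compartments CNS compartments to sum (default the six brain
#'   regions).
#' @return list with `sums` (data.frame subject/group/total), `test`
#'   (from [two_sample_t()]), `dropped` (subject ids), `note`.
#' @export
cns_combined <- function(table, lipid, group_a, group_b,
                         compartments = c("HYP", "CER", "STR", "THAL",
                                          "CTX", "HIPP")) {
  d <- table[table$lipid == lipid & table$compartment %in% compartments &
               table$group %in% c(group_a, group_b), , drop = FALSE]
  sums <- do.call(rbind, lapply(split(d, d[c("subject", "group")], drop = TRUE),
    function(s) {
      data.frame(subject = s$subject[1], group = s$group[1],
                 total = sum(s$concentration),
                 complete = length(unique(s$compartment)) ==
                   length(compartments))
    }))
  rownames(sums) <- NULL
  dropped <- sums$subject[!sums$complete]
  sums <- sums[sums$complete, c("subject", "group", "total")]
  test <- two_sample_t(sums$total[sums$group == group_a],
                       sums$total[sums$group == group_b])
  list(sums = sums, test = test, dropped = dropped,
       note = if (length(dropped))
         sprintf("dropped %d subject(s) with incomplete regions",
                 length(dropped)) else "")
}

#' Fold change between two group means, expressed as >= 1
#'
#' Magnitude is `max(means)/min(means)`; the direction flag carries the
#' sign (`"increase"` when the treated mean exceeds vehicle). Equal
#' means tie-break to `"increase"` with fold 1.
#'
#' @param mean_treated,mean_vehicle positive group means.
#' @return list with `fold` (>= 1) and `direction`.
#' @export
fold_change <- function(mean_treated, mean_vehicle) {
  if (mean_treated <= 0 || mean_vehicle <= 0)
    stop_validation("fold change needs positive means (detection-status path handles zeros)")
  list(fold = max(mean_treated, mean_vehicle) / min(mean_treated, mean_vehicle),
       direction = if (mean_treated >= mean_vehicle) "increase" else "decrease")
}

#' Fold-change arrow bins
#'
#' The heatmap's effect-size encoding: 1 arrow for a 1-1.49-fold
#' difference, 2 for 1.5-1.99, 3 for 2-2.99, 4 for 3-9.99, and 5 for
#' tenfold or more. Bin edges belong to the upper bin (a 1.5-fold
#' difference gets 2 arrows).
#'
#' @param fold fold difference, >= 1 (normalize with [fold_change()]).
#' @return integer arrow count 1-5.
#' @export
#' @examples
#' arrow_bin(c(1.2, 1.7, 2.5, 3.5, 12))  # 1 2 3 4 5
arrow_bin <- function(fold) {
  if (any(fold < 1)) stop_validation("fold must be >= 1; normalize first")
  as.integer(cut(fold, breaks = c(1, 1.5, 2, 3, 10, Inf),
                 right = FALSE, include.lowest = TRUE))
}

#' Significance shade bins
#'
#' `p < 0.05` is a dark shade, `0.05 <= p < 0.1` a light shade
#' (boundary p = 0.05 is assigned light), anything else unshaded.
#'
#' @param p p-value(s) in [0, 1].
#' @return character: `"dark"`, `"light"` or `"none"`.
#' @export
shade_bin <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_validation("p outside [0, 1]")
  out <- rep("none", length(p))
  out[!is.na(p) & p < 0.1] <- "light"
  out[!is.na(p) & p < 0.05] <- "dark"
  out[is.na(p)] <- NA_character_
  out
}

#' Detection status of a lipid measurement set
#'
#' `"BDL"` (below detectable limits) when no sample has a detectable
#' value; `"BAL"` (below analytical limits) when some do but fewer than
#' `n_required` — too few for a statistical determination; `"ok"`
#' otherwise.
#'
#' @param detected logical vector of detection flags for one group.
#' @param n_required minimum detectable samples for analysis (default 3).
#' @return `"ok"`, `"BDL"` or `"BAL"`.
#' @export
detection_status <- function(detected, n_required = 3) {
  n_det <- sum(detected)
  if (n_det == 0) "BDL" else if (n_det < n_required) "BAL" else "ok"
}

#' Build the differential lipid heatmap grid
#'
#' For every lipid x compartment cell, the treated and vehicle groups
#' are processed through the full rule chain: detection status, 2-SD
#' outlier exclusion per group (on detected values), pooled t-test,
#' fold change on the post-exclusion means, arrow bin and significance
#' shade. A cell is `BDL` when neither group has any detectable sample
#' and `BAL` when either group has fewer than `n_required` detectable
#' samples.
#'
#' @param table long-format lipid table.
#' @param treated,vehicle group labels to compare.
#' @param n_required minimum detectable samples per group.
#' @return data.frame, one row per lipid x compartment: `status`,
#'   `mean_treated`, `mean_vehicle`, `p`, `fold`, `direction`, `arrows`,
#'   `shade`, `n_excluded`.
#' @export
build_heatmap <- function(table, treated, vehicle, n_required = 3) {
  need <- c("subject", "group", "compartment", "lipid", "concentration",
            "detected")
  if (!all(need %in% names(table)))
    stop_validation("lipid table needs columns: %s",
                    paste(need, collapse = ", "))
  d <- table[table$group %in% c(treated, vehicle), , drop = FALSE]
  cells <- unique(d[c("lipid", "compartment")])
  cells <- cells[order(cells$lipid, cells$compartment), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- d[d$lipid == cells$lipid[i] &
                d$compartment == cells$compartment[i], , drop = FALSE]
    trt <- cell[cell$group == treated, ]
    veh <- cell[cell$group == vehicle, ]
    out <- data.frame(lipid = cells$lipid[i],
                      compartment = cells$compartment[i],
                      status = "ok", mean_treated = NA_real_,
                      mean_vehicle = NA_real_, p = NA_real_,
                      fold = NA_real_, direction = NA_character_,
                      arrows = NA_integer_, shade = NA_character_,
                      n_excluded = 0L)
    if (sum(trt$detected) + sum(veh$detected) == 0) {
      out$status <- "BDL"
      return(out)
    }
    if (detection_status(trt$detected, n_required) != "ok" ||
        detection_status(veh$detected, n_required) != "ok") {
      out$status <- "BAL"
      return(out)
    }
    a <- exclude_outliers(trt$concentration[trt$detected])
    b <- exclude_outliers(veh$concentration[veh$detected])
    out$n_excluded <- length(a$excluded) + length(b$excluded)
    test <- two_sample_t(a$values, b$values)
    out$mean_treated <- test$mean_a
    out$mean_vehicle <- test$mean_b
    out$p <- test$p
    if (test$mean_a > 0 && test$mean_b > 0) {
      fc <- fold_change(test$mean_a, test$mean_b)
      out$fold <- fc$fold
      out$direction <- fc$direction
      out$arrows <- arrow_bin(fc$fold)
    }
    out$shade <- shade_bin(test$p)
    out
  })
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  grid
}

#' One-way ANOVA with Fisher LSD post-hoc for a dose curve
#'
#' Classical one-way ANOVA across dose groups; when the omnibus test is
#' significant at `alpha`, unadjusted pairwise comparisons are computed
#' with the pooled within-group mean square (Fisher's Least Significant
#' Difference). Pairwise results are withheld (NULL) when the omnibus
#' gate fails.
#'
#' @param values numeric responses.
#' @param groups group labels, same length.
#' @param alpha omnibus gate (default 0.05).
#' @return list with `F`, `df`, `p`, and `pairwise` (data.frame with
#'   `group_a`, `group_b`, `t`, `p`, or NULL).
#' @export
dose_anova_lsd <- function(values, groups, alpha = 0.05) {
  an <- one_way_anova(values, groups)
  pairwise <- NULL
  if (!is.na(an$p) && an$p < alpha) {
    g <- factor(groups)
    k <- nlevels(g)
    n <- length(values)
    ns <- tapply(values, g, length)
    means <- tapply(values, g, mean)
    mse <- sum(tapply(values, g, function(x) sum((x - mean(x))^2))) / (n - k)
    combs <- utils::combn(levels(g), 2)
    pairwise <- do.call(rbind, apply(combs, 2, function(pr) {
      se <- sqrt(mse * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
      tt <- (means[pr[1]] - means[pr[2]]) / se
      data.frame(group_a = pr[1], group_b = pr[2], t = unname(tt),
                 p = unname(2 * stats::pt(-abs(tt), n - k)))
    }, simplify = FALSE))
    rownames(pairwise) <- NULL
  }
  c(an, list(pairwise = pairwise))
}
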
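#' One-way ANOVA across treatment groups
#'
#' Classical between/within decomposition with F on (k-1, n-k) degrees
#' of freedom (via [stats::aov()]). Degenerate conventions: zero
#' within-group variance gives F = 0, p = 1 when the group means are
#' also equal, and F = Inf, p = 0 otherwise.
#'
#' @param values numeric responses.
#' @param groups group labels, same length; >= 2 groups of >= 2.
#' @return list with `F`, `df` (numerator, denominator), `p`.
#' @export
#' @examples
#' one_way_anova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))$F  # 1.5
one_way_anova <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop_validation("need >= 2 groups with >= 2 observations each")
  ssw <- sum(tapply(values, g, function(x) sum((x - mean(x))^2)))
  if (ssw == 0) {
    means <- tapply(values, g, mean)
    equal <- length(unique(means)) == 1L
    return(list(F = if (equal) 0 else Inf,
                df = c(nlevels(g) - 1L, length(values) - nlevels(g)),
                p = if (equal) 1 else 0))
  }
  fit <- stats::aov(values ~ g)
  an <- stats::anova(fit)
  list(F = an[["F value"]][1],
       df = an$Df,
       p = an[["Pr(>F)"]][1])
}

#' Novel-object investigation ratio
#'
#' `IR = novel / (novel + familiar)`. Subjects with zero total
#' investigation time have no defined ratio: the result is `NA` with a
#' `flagged` attribute so they can be excluded and logged (as done for
#' animals that never attend to either object).
#'
#' @param novel,familiar investigation times in seconds (>= 0).
#' @return numeric IR in [0, 1]; `NA` where the total is zero.
#' @export
#' @examples
#' investigation_ratio(30, 30)  # 0.5
investigation_ratio <- function(novel, familiar) {
  if (any(novel < 0 | familiar < 0))
    stop_validation("investigation times must be >= 0")
  total <- novel + familiar
  ir <- ifelse(total > 0, novel / total, NA_real_)
  attr(ir, "flagged") <- which(total == 0)
  ir
}

#' One-sample test of investigation ratios against chance
#'
#' Two-tailed one-sample t-test of the IRs against 0.5. `NA` ratios
#' (undefined subjects) are dropped first. Zero variance degenerates to
#' p = 1 at the chance mean and p = 0 away from it.
#'
#' @param irs numeric investigation ratios.
#' @param chance null value (default 0.5).
#' @return list with `t`, `df`, `p`, `mean`, `n`.
#' @export
#' @examples
#' ir_vs_chance(c(0.6, 0.7, 0.8))  # t = 3.464, p ~ 0.074
ir_vs_chance <- function(irs, chance = 0.5) {
  irs <- irs[!is.na(irs)]
  n <- length(irs)
  if (n < 2) stop_validation("need >= 2 defined investigation ratios")
  if (stats::sd(irs) == 0) {
    eq <- irs[1] == chance
    return(list(t = if (eq) 0 else sign(irs[1] - chance) * Inf,
                df = n - 1, p = if (eq) 1 else 0, mean = irs[1], n = n))
  }
  tt <- stats::t.test(irs, mu = chance)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean = mean(irs), n = n)
}

#' Behavioral statistics for a long-format measure table
#'
#' Runs the measure-appropriate test over a table of open-field, novel
#' object and tail-flick records: one-way ANOVA across groups for every
#' measure, plus the one-sample chance test per group for `ir`.
#'
#' @param table data.frame with `subject`, `group`, `measure`, `value`.
#' @return list with `anova` (data.frame measure/F/p) and `ir_chance`
#'   (data.frame group/t/p, or NULL when no `ir` measure is present).
#' @export
behavior_stats <- function(table) {
  need <- c("subject", "group", "measure", "value")
  if (!all(need %in% names(table)))
    stop_validation("behavior table needs columns: %s",
                    paste(need, collapse = ", "))
  an <- do.call(rbind, lapply(split(table, table$measure), function(d) {
    res <- one_way_anova(d$value, d$group)
    data.frame(measure = d$measure[1], F = res$F,
               df1 = res$df[1], df2 = res$df[2], p = res$p)
  }))
  rownames(an) <- NULL
  ir_chance <- NULL
  if ("ir" %in% table$measure) {
    d <- table[table$measure == "ir", ]
    ir_chance <- do.call(rbind, lapply(split(d, d$group), function(gd) {
      res <- ir_vs_chance(gd$value)
      data.frame(group = gd$group[1], t = res$t, df = res$df, p = res$p,
                 mean_ir = res$mean, n = res$n)
    }))
    rownames(ir_chance) <- NULL
  }
  list(anova = an, ir_chance = ir_chance)
}
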
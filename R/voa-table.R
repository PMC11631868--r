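#' Kruskal-Wallis dose-response test per region
#'
#' Rank-based one-way test of voxel counts across dose groups, one test
#' per atlas region, with the usual tie correction (via
#' [stats::kruskal.test()]). Degenerate regions where every observation
#' is identical get H = 0, p = 1 (the tie correction is 0/0 there; the
#' data carry no ordering information).
#'
#' @param counts data.frame with columns `region_id`, `subject`, `count`,
#'   `group` — one row per region x subject.
#' @return data.frame with `region_id`, `H`, `df`, `p`.
#' @export
#' @examples
#' df <- data.frame(region_id = 1, subject = 1:9,
#'                  count = 1:9, group = rep(c("a", "b", "c"), each = 3))
#' kruskal_wallis_by_region(df)$H  # 7.2
kruskal_wallis_by_region <- function(counts) {
  need <- c("region_id", "subject", "count", "group")
  if (!all(need %in% names(counts)))
    stop_validation("counts needs columns: %s", paste(need, collapse = ", "))
  res <- lapply(split(counts, counts$region_id), function(d) {
    g <- factor(d$group)
    if (nlevels(g) < 2 || any(table(g) < 1))
      stop_validation("region %s: need >= 2 groups with observations",
                      d$region_id[1])
    if (length(unique(d$count)) == 1L) {
      data.frame(region_id = d$region_id[1], H = 0,
                 df = nlevels(g) - 1L, p = 1)
    } else {
      kt <- stats::kruskal.test(d$count, g)
      data.frame(region_id = d$region_id[1],
                 H = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p = kt$p.value)
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$region_id), , drop = FALSE]
}

#' Rank-based effect size for a Kruskal-Wallis test
#'
#' The epsilon-squared style estimate `(H - k + 1) / (n - k)`, floored at
#' zero. Under the null E[H] = k - 1, so the null expectation maps to 0;
#' the maximum (perfect separation, no ties) approaches 1.
#'
#' @param H Kruskal-Wallis statistic.
#' @param k number of groups.
#' @param n total number of observations (must exceed `k`).
#' @return effect size in [0, 1+].
#' @export
#' @examples
#' omega_squared(7.2, k = 3, n = 9)  # 0.8667
omega_squared <- function(H, k, n) {
  if (any(n <= k)) stop_validation("effect size undefined for n <= k")
  pmax(0, (H - k + 1) / (n - k))
}

#' Build the regional volume-of-activation table for a study
#'
#' Aggregates per-subject region counts into the standard dose-response
#' table: per-group mean and SE of the voxel counts, Kruskal-Wallis H
#' and p per region, and the rank-based effect size.
#'
#' @param subject_counts data.frame with `region_id`, `region`,
#'   `subject`, `group` and a count column.
#' @param sign `"negative"` or `"positive"` — which voxel count column
#'   (`n_negative` / `n_positive`) to analyze; ignored if `count` is
#'   already present.
#' @return data.frame, one row per region: group means/SEs (columns
#'   `mean_<group>`, `se_<group>`), `H`, `p`, `omega_sq`.
#' @export
region_activation_table <- function(subject_counts, sign = c("negative", "positive")) {
  sign <- match.arg(sign)
  d <- subject_counts
  if (!"count" %in% names(d)) {
    col <- paste0("n_", sign)
    if (!col %in% names(d))
      stop_validation("no '%s' or 'count' column in subject counts", col)
    d$count <- d[[col]]
  }
  se <- function(x) stats::sd(x) / sqrt(length(x))
  groups <- unique(d$group)
  split_reg <- split(d, d$region_id)
  stats_tab <- do.call(rbind, lapply(split_reg, function(r) {
    row <- data.frame(region_id = r$region_id[1],
                      region = if ("region" %in% names(r)) r$region[1] else
                        as.character(r$region_id[1]))
    for (g in groups) {
      v <- r$count[r$group == g]
      row[[paste0("mean_", g)]] <- mean(v)
      row[[paste0("se_", g)]] <- se(v)
    }
    row
  }))
  kw <- kruskal_wallis_by_region(d[, c("region_id", "subject", "count", "group")])
  out <- merge(stats_tab, kw, by = "region_id", sort = TRUE)
  n_obs <- as.data.frame(table(region_id = d$region_id),
                         responseName = "n_obs", stringsAsFactors = FALSE)
  n_obs$region_id <- utils::type.convert(n_obs$region_id, as.is = TRUE)
  out <- merge(out, n_obs, by = "region_id", sort = TRUE)
  out$omega_sq <- omega_squared(out$H, k = length(groups), n = out$n_obs)
  rownames(out) <- NULL
  out
}

#' Rank a regional table by significance and summarize across-region FDR
#'
#' Rows are ordered by ascending p (ties broken by region name for a
#' deterministic layout). The significant view keeps rows with
#' `p < alpha` strictly. The across-region FDR summary applies the
#' Benjamini-Hochberg step-up over all tested regions and reports the
#' largest raw p still called significant at level `alpha` (the realized
#' FDR cut), plus BH-adjusted p-values on the ranked table.
#'
#' @param tab data.frame with at least `region` and `p`.
#' @param alpha significance level (default 0.05, strict `<`).
#' @return list with `ranked` (full table, sorted, with `p_adj`),
#'   `significant` (subset), `n_significant`, and `fdr_cut`.
#' @export
rank_table <- function(tab, alpha = 0.05) {
  if (nrow(tab) == 0)
    return(list(ranked = tab, significant = tab, n_significant = 0L,
                fdr_cut = NA_real_))
  ord <- order(tab$p, tab$region)
  ranked <- tab[ord, , drop = FALSE]
  ranked$p_adj <- stats::p.adjust(ranked$p, method = "BH")
  rownames(ranked) <- NULL
  sig <- ranked[ranked$p < alpha, , drop = FALSE]
  bh_pass <- ranked$p[ranked$p_adj <= alpha]
  list(ranked = ranked,
       significant = sig,
       n_significant = nrow(sig),
       fdr_cut = if (length(bh_pass)) max(bh_pass) else NA_real_)
}

#' Run the full activation analysis for a set of subjects
#'
#' @param bolds list of [bold4d()] objects (any mix of groups).
#' @param atlas an [atlas_labels()].
#' @param config a [run_config()].
#' @return list with `subject_counts` (long data.frame), `negative` and
#'   `positive` region tables (from [region_activation_table()]), and
#'   per-subject `maps`.
#' @export
run_activation_study <- function(bolds, atlas, config = run_config()) {
  maps <- lapply(bolds, subject_activation, atlas = atlas, config = config)
  long <- do.call(rbind, lapply(seq_along(bolds), function(i) {
    cbind(maps[[i]]$counts,
          subject = bolds[[i]]$subject,
          group = bolds[[i]]$group)
  }))
  rownames(long) <- NULL
  list(subject_counts = long,
       negative = region_activation_table(long, "negative"),
       positive = region_activation_table(long, "positive"),
       maps = maps)
}
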
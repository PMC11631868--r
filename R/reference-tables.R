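#' Bundled reference volume-of-activation tables
#'
#' Two published-style regional tables from a four-dose awake-rat BOLD
#' study over a 173-region atlas, shipped with the package as plain CSV:
#' the regions showing a dose-dependent change in negative volume of
#' activation (`"negative"`, 70 rows, p-ranked, printed down to
#' p = 0.05) and those showing a change in positive volume of
#' activation (`"positive"`, 26 rows). Columns: `region`, per-group
#' `mean_*` / `se_*` voxel counts (vehicle, 3, 10, 30 mg/kg), `p`
#' (Kruskal-Wallis) and `omega_sq` (reported effect size). Used as
#' worked input for [rank_table()] and in the package's consistency
#' checks.
#'
#' @param sign `"negative"` or `"positive"`.
#' @return data.frame as described.
#' @export
#' @examples
#' tab <- voa_reference_table("negative")
#' rank_table(tab)$n_significant  # 69 regions below p = 0.05
voa_reference_table <- function(sign = c("negative", "positive")) {
  sign <- match.arg(sign)
  path <- system.file("extdata",
                      paste0(sign, "_voa_regions.csv"),
                      package = "phmrikit", mustWork = TRUE)
  read_table(path, required = c("region", "p", "omega_sq"),
             numeric = c("p", "omega_sq"))
}
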
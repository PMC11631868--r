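# Independent oracles used across the suite. These deliberately do not
# share code with the package implementations they check.

# brute-force Benjamini-Hochberg step-up: scan ranks from the top and
# admit everything at or below the largest satisfying rank
oracle_bh <- function(p, q, cV = 1) {
  V <- length(p)
  o <- order(p)
  pass <- rep(FALSE, V)
  for (i in V:1) {
    if (p[o[i]] <= i / V * q * cV) {
      pass[o[seq_len(i)]] <- TRUE
      break
    }
  }
  pass
}

# Kruskal-Wallis H from the rank formula with explicit tie correction
oracle_kw_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  Rg <- tapply(r, groups, sum)
  ng <- tapply(r, groups, length)
  H <- 12 / (n * (n + 1)) * sum(Rg^2 / ng) - 3 * (n + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# adjusted Rand index between two label vectors
oracle_ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# convenience: null lipid spec set for calibration runs
null_lipid_specs <- function(n_lipids = 3,
                             compartments = c("STR", "THAL"),
                             mean = 10, cv = 0.3) {
  out <- list()
  for (cp in compartments)
    for (i in seq_len(n_lipids))
      out[[length(out) + 1L]] <- lipid_effect_spec(
        lipid = paste0("lip", i), compartment = cp,
        group_means = c(vehicle = mean, `30mg` = mean), cv = cv)
  out
}
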
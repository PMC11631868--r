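small_design <- function(n = 2, seed = 1, groups = c("vehicle", "3mg")) {
  bold_design(n_acquisitions = 40, baseline_window = c(1, 10),
              response_window = c(21, 40),
              groups = data.frame(label = groups,
                                  dose = seq_along(groups),
                                  n_subjects = n),
              seed = seed)
}

test_that("identical seeds and specs give bit-identical outputs", {
  at <- synth_atlas(dim = c(10, 10, 4), n_regions = 3)
  eff <- list(region_effect_spec(2, c(`3mg` = -3), 0.5))
  a <- generate_bold(small_design(seed = 9), at, eff, noise_sd = 0.7)
  b <- generate_bold(small_design(seed = 9), at, eff, noise_sd = 0.7)
  expect_identical(a$subjects[[1]]$data, b$subjects[[1]]$data)
  expect_identical(a$truth, b$truth)
  c_ <- generate_bold(small_design(seed = 10), at, eff, noise_sd = 0.7)
  expect_false(identical(a$subjects[[1]]$data, c_$subjects[[1]]$data))

  s1 <- generate_restingstate(network_spec(6, seed = 4))
  s2 <- generate_restingstate(network_spec(6, seed = 4))
  expect_identical(s1$series, s2$series)

  l1 <- generate_lipid_table(list(lipid_effect_spec("PEA", "plasma",
        c(vehicle = 1, `30mg` = 50))), seed = 5)
  l2 <- generate_lipid_table(list(lipid_effect_spec("PEA", "plasma",
        c(vehicle = 1, `30mg` = 50))), seed = 5)
  expect_identical(l1$table, l2$table)

  b1 <- generate_behavior_table(seed = 6)
  b2 <- generate_behavior_table(seed = 6)
  expect_identical(b1$table, b2$table)
})

test_that("no effects and no noise give constant series and zero maps", {
  at <- synth_atlas(dim = c(8, 8, 3), n_regions = 2)
  sim <- generate_bold(small_design(), at, effects = list(), noise_sd = 0)
  s <- sim$subjects[[1]]
  expect_true(all(s$data == 100))
  pc <- percent_change_map(s, c(1, 10), c(21, 40))
  expect_true(all(pc == 0))
  expect_equal(nrow(sim$truth), 0L)
})

test_that("a -3% step at responder fraction 1 scales the window exactly", {
  at <- synth_atlas(dim = c(8, 8, 3), n_regions = 2)
  eff <- list(region_effect_spec(1, c(`3mg` = -3), responder_fraction = 1))
  sim <- generate_bold(small_design(), at, eff, noise_sd = 0)
  s <- sim$subjects[["3mg_s01"]]
  vox <- which(at$labels == 1)
  m <- matrix(s$data, nrow = prod(dim(at$labels)))
  expect_equal(unique(rowMeans(m[vox, 21:40, drop = FALSE]) /
                        rowMeans(m[vox, 1:10, drop = FALSE])), 0.97)
  # vehicle subjects untouched
  expect_true(all(sim$subjects[["vehicle_s01"]]$data == 100))
})

test_that("noisy responder counts are recovered within the oracle band", {
  # Monte-Carlo tolerance: at -3% with noise SD 0.5 on the window means
  # the per-voxel detection probability is ~1 and false positives are
  # blocked by the 1% magnitude threshold, so counts sit within 15% of
  # the injected responder number (the band the oracle run supports).
  at <- synth_atlas(dim = c(12, 12, 4), n_regions = 3)
  des <- bold_design(groups = data.frame(label = c("vehicle", "3mg"),
                                         dose = c(0, 3), n_subjects = c(6, 6)),
                     seed = 13)
  eff <- list(region_effect_spec(2, c(`3mg` = -3), responder_fraction = 0.5))
  sim <- generate_bold(des, at, eff, noise_sd = 0.5)
  res <- run_activation_study(sim$subjects, at)
  meas <- subset(res$subject_counts, region_id == 2 & group == "3mg")
  truth <- subset(sim$truth, region_id == 2 & group == "3mg")
  ratio <- mean(meas$n_negative) / mean(truth$n_responders)
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.15)
  # vehicle region stays near zero
  veh <- subset(res$subject_counts, region_id == 2 & group == "vehicle")
  expect_lt(mean(veh$n_negative), 0.05 * mean(truth$n_responders))
})

test_that("generator validation catches bad regions and windows", {
  at <- synth_atlas(dim = c(8, 8, 3), n_regions = 2)
  expect_error(generate_bold(small_design(), at,
                             list(region_effect_spec(9, c(`3mg` = -1)))),
               "unknown region")
  expect_error(bold_design(baseline_window = c(5, 45),
                           response_window = c(40, 80)), "must end before")
  expect_error(bold_design(groups = data.frame(label = "a", dose = 0,
                                               n_subjects = 1)), ">= 2")
  expect_error(region_effect_spec(1, c(`3mg` = -1), responder_fraction = 2),
               "responder_fraction")
})

test_that("resting-state generator honors the block covariance", {
  # independent nodes: sample correlations centered on zero
  s0 <- generate_restingstate(network_spec(8, within_block_r = 0,
                                           between_block_r = 0,
                                           series_length = 200, seed = 14))
  r0 <- pearson_matrix(s0$series)
  expect_lt(mean(abs(r0[upper.tri(r0)])), 0.12)  # ~E|r| = 0.056 at T = 200
  # two blocks: within-block correlations dominate between-block
  sp <- network_spec(10, rep(1:2, each = 5), 0.8, 0, 150, seed = 15)
  rs <- generate_restingstate(sp)
  r <- pearson_matrix(rs$series)
  same <- outer(rs$blocks, rs$blocks, "==") & upper.tri(r)
  diff_ <- !outer(rs$blocks, rs$blocks, "==") & upper.tri(r)
  expect_gt(mean(r[same]), mean(r[diff_]) + 0.3)
  # single node: 1 x T matrix, nothing to correlate
  s1 <- generate_restingstate(network_spec(1, block_assignment = 1,
                                           series_length = 50, seed = 16))
  expect_equal(dim(s1$series), c(1L, 50L))
  # non-PSD request rejected with the offending r values named
  expect_error(network_spec(6, rep(1:3, each = 2), within_block_r = 0.1,
                            between_block_r = -0.9),
               "non-PSD")
})

test_that("lipid generator: zero-CV exactness, censoring and outliers", {
  specs <- list(lipid_effect_spec("PEA", "plasma",
                                  c(vehicle = 1, `30mg` = 50), cv = 0))
  out <- generate_lipid_table(specs, n_per_group = 5, seed = 17)
  m <- tapply(out$table$concentration, out$table$group, mean)
  expect_equal(unname(m["30mg"] / m["vehicle"]), 50)   # exact at cv = 0
  expect_equal(out$truth$true_fold[out$truth$group == "30mg"], 50)

  # full censoring flags every record
  bdl <- generate_lipid_table(list(lipid_effect_spec("x", "STR",
        c(vehicle = 2, `30mg` = 2), p_below_detection = 1)), seed = 18)
  expect_true(all(!bdl$table$detected))
  expect_true(all(bdl$table$concentration == 0))

  # injected outliers sit > 2 SD from the uncontaminated group
  set.seed(19)
  sp <- list(lipid_effect_spec("y", "CER", c(vehicle = 10, `30mg` = 10),
                               cv = 0.2, outlier_rate = 0.2))
  tab <- generate_lipid_table(sp, n_per_group = 10, seed = 19)$table
  for (g in unique(tab$group)) {
    v <- tab$concentration[tab$group == g]
    res <- exclude_outliers(v)
    # any injected outlier is flagged by the single-pass rule at n = 10
    if (max(v) > mean(v[-which.max(v)]) + 2.5 * sd(v[-which.max(v)]))
      expect_gt(length(res$excluded), 0)
  }
})

test_that("fold-change recovery at cv 0.3 sits within the sampling band", {
  # the 1,000-rep oracle for n = 5, cv = 0.3 puts the middle 95% of
  # fold-change estimates for a 50-fold effect within roughly +/-35%
  specs <- list(lipid_effect_spec("PEA", "plasma",
                                  c(vehicle = 1, `30mg` = 50), cv = 0.3))
  folds <- vapply(1:40, function(i) {
    tab <- generate_lipid_table(specs, n_per_group = 5, seed = 100 + i)$table
    hm <- build_heatmap(tab, "30mg", "vehicle")
    hm$fold
  }, numeric(1))
  expect_gt(median(folds), 35)
  expect_lt(median(folds), 70)
  expect_true(all(folds > 20 & folds < 120))
})

test_that("behavior generator output feeds the stats layer unmodified", {
  sim <- generate_behavior_table(n_per_group = 6, seed = 20)
  expect_setequal(names(sim$table), c("subject", "group", "measure", "value"))
  irs <- sim$table$value[sim$table$measure == "ir"]
  expect_true(all(irs >= 0 & irs <= 1))
  times <- sim$table$value[sim$table$measure %in%
                             c("wall_time", "corner_time", "center_time")]
  expect_true(all(times >= 0))
  expect_silent(behavior_stats(sim$table))
})
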
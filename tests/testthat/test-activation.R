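make_bold <- function(mat, tr = 6) {
  # mat: voxels x time; wrapped into an x-by-1-by-1 grid
  bold4d(array(mat, dim = c(nrow(mat), 1, 1, ncol(mat))), tr = tr)
}

test_that("percent change is exact on constructed series", {
  # constant series -> 0; forced 102 vs 100 -> +2; 99 vs 100 -> -1 boundary
  mat <- rbind(rep(100, 10),
               c(rep(100, 5), rep(102, 5)),
               c(rep(100, 5), rep(99, 5)))
  b <- make_bold(mat)
  pc <- percent_change_map(b, c(1, 5), c(6, 10))
  expect_equal(as.vector(pc), c(0, 2, -1))
})

test_that("zero-baseline voxels are marked invalid, not fatal", {
  mat <- rbind(c(rep(0, 5), rep(5, 5)), rep(100, 10))
  b <- make_bold(mat)
  expect_warning(pc <- percent_change_map(b, c(1, 5), c(6, 10)),
                 "zero baseline")
  expect_true(is.na(pc[1, 1, 1]))
  expect_equal(attr(pc, "qc")$n_invalid, 1L)
})

test_that("window validation rejects overlap and bad bounds", {
  b <- make_bold(matrix(100, 2, 20))
  expect_error(percent_change_map(b, c(1, 10), c(5, 15)), "must end before")
  expect_error(percent_change_map(b, c(0, 5), c(10, 15)), "outside")
  expect_error(percent_change_map(b, c(1, 5), c(10, 25)), "outside")
})

test_that("voxel Welch test matches stats::t.test and honors conventions", {
  set.seed(41)
  nvox <- 100
  base <- matrix(rnorm(nvox * 8, 100, 2), nvox, 8)
  resp <- matrix(rnorm(nvox * 12, 101, 3), nvox, 12)
  b <- make_bold(cbind(base, resp))
  p <- as.vector(voxel_ttest(b, c(1, 8), c(9, 20)))
  p_ref <- vapply(seq_len(nvox), function(i)
    t.test(resp[i, ], base[i, ])$p.value, numeric(1))
  expect_equal(p, p_ref, tolerance = 1e-10)

  # a response that is a permutation of the baseline: t = 0, p = 1
  b2 <- make_bold(matrix(c(1, 2, 3, 4, 3, 1, 4, 2), 1))
  expect_equal(as.vector(voxel_ttest(b2, c(1, 4), c(5, 8))), 1)

  # zero-variance conventions
  b3 <- make_bold(rbind(c(rep(1, 4), rep(1, 4)), c(rep(1, 4), rep(2, 4))))
  expect_equal(as.vector(voxel_ttest(b3, c(1, 4), c(5, 8))), c(1, 0))
})

test_that("ranked-p filter reproduces the hand-evaluated step-up case", {
  p <- c(0.01, 0.05, 0.10, 0.5, 0.9)
  # thresholds at q = 0.2, cV = 1: 0.04 0.08 0.12 0.16 0.20 -> ranks 1-3
  expect_equal(ranked_p_filter(p, q = 0.2, cV = 1),
               c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_false(any(ranked_p_filter(rep(1, 6), 0.2)))
  expect_true(all(ranked_p_filter(rep(0, 6), 0.2)))
  expect_equal(ranked_p_filter(numeric(0)), logical(0))
})

test_that("ranked-p filter equals the brute-force step-up oracle", {
  set.seed(7)
  for (rep in 1:200) {
    V <- sample(1:50, 1)
    p <- round(runif(V), sample(1:3, 1))   # rounding forces ties
    q <- sample(c(0.05, 0.2, 0.5, 1), 1)
    expect_identical(ranked_p_filter(p, q), oracle_bh(p, q))
  }
})

test_that("lowering q never admits more voxels (monotonicity)", {
  set.seed(8)
  for (rep in 1:50) {
    p <- runif(sample(2:40, 1))
    n_loose <- sum(ranked_p_filter(p, q = 0.2))
    n_tight <- sum(ranked_p_filter(p, q = 0.05))
    expect_lte(n_tight, n_loose)
  }
})

test_that("voxel classification applies filter and inclusive threshold", {
  pct <- array(c(0.5, -1, -5, 1.0, 2), dim = c(5, 1, 1))
  pass <- array(c(TRUE, TRUE, FALSE, TRUE, TRUE), dim = c(5, 1, 1))
  cls <- classify_voxels(pct, pass, threshold = 1)
  expect_equal(as.vector(cls),
               c("null", "negative", "null", "positive", "positive"))
  # raising the threshold never increases signed counts
  cls2 <- classify_voxels(pct, pass, threshold = 2)
  expect_lte(sum(cls2 != "null"), sum(cls != "null"))
})

test_that("region counts match a constructed fixture", {
  lab <- array(0L, dim = c(5, 4, 1))
  lab[1:5, 1:4, 1] <- 1L                      # one region of 20 voxels
  at <- atlas_labels(lab, data.frame(id = 1, name = "r1"))
  cls <- array("null", dim = c(5, 4, 1))
  cls[1:4, 1, 1] <- "negative"; cls[1:3, 2, 1] <- "negative"  # 7 negative
  cls[5, 4, 1] <- "positive"
  cnt <- region_voxel_counts(cls, at)
  expect_equal(cnt$n_negative, 7L)
  expect_equal(cnt$n_positive, 1L)
  expect_equal(cnt$n_voxels, 20L)
  expect_error(region_voxel_counts(cls[1:4, , , drop = FALSE], at),
               "does not match")
  # all-null map
  cnt0 <- region_voxel_counts(array("null", dim = dim(lab)), at)
  expect_equal(cnt0$n_negative + cnt0$n_positive, 0L)
})

test_that("composite map: identity, symmetry and order invariance", {
  set.seed(9)
  m <- array(rnorm(4 * 3 * 2), dim = c(4, 3, 2))
  expect_equal(composite_map(list(m)), m)
  z <- composite_map(list(m, -m))
  expect_true(all(abs(z) < 1e-12))
  m2 <- array(rnorm(4 * 3 * 2), dim = c(4, 3, 2))
  expect_equal(composite_map(list(m, m2)), composite_map(list(m2, m)))
})

test_that("composite trilinear sampling interpolates the midpoint", {
  # neighboring values 0 and 2 along x; shift composite grid by half a
  # voxel so composite voxel 0 samples subject coordinate 0.5 -> 1.0
  m <- array(c(0, 2), dim = c(2, 1, 1))
  tf <- diag(4); tf[1, 4] <- -0.5       # subject -> composite shift
  cm <- composite_map(list(m), list(subject_transform(tf)),
                      dim_out = c(1, 1, 1))
  expect_equal(cm[1, 1, 1], 1.0)
})

test_that("singular transforms are rejected naming the subject", {
  bad <- diag(4); bad[1, 1] <- 0
  expect_error(subject_transform(bad, subject = "r7"), "r7")
})

test_that("Kruskal-Wallis matches hand computation and the rank oracle", {
  df <- data.frame(region_id = 1, subject = 1:9, count = 1:9,
                   group = rep(c("a", "b", "c"), each = 3))
  kw <- kruskal_wallis_by_region(df)
  expect_equal(kw$H, 7.2)                 # rank sums 6, 15, 24
  expect_equal(kw$df, 2L)

  same <- data.frame(region_id = 1, subject = 1:6, count = rep(3, 6),
                     group = rep(c("a", "b"), each = 3))
  kw0 <- kruskal_wallis_by_region(same)
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p, 1)

  set.seed(10)
  for (rep in 1:20) {
    v <- round(rnorm(12), 1)              # ties likely
    g <- rep(c("a", "b", "c"), each = 4)
    d <- data.frame(region_id = 1, subject = 1:12, count = v, group = g)
    expect_equal(kruskal_wallis_by_region(d)$H, oracle_kw_h(v, g),
                 tolerance = 1e-10)
  }
})

test_that("rank-based effect size behaves at its anchors", {
  expect_equal(omega_squared(7.2, 3, 9), (7.2 - 2) / 6)
  expect_equal(omega_squared(2, 3, 9), 0)    # H = k - 1: null expectation
  expect_equal(omega_squared(0, 3, 9), 0)    # floored
  expect_error(omega_squared(1, 3, 3), "undefined")
})

test_that("significance ranking of the bundled reference tables", {
  neg <- voa_reference_table("negative")
  rk <- rank_table(neg, alpha = 0.05)
  expect_equal(rk$n_significant, 69L)        # strict p < 0.05
  expect_equal(nrow(neg), 70L)
  expect_true(!is.unsorted(rk$ranked$p))

  pos <- voa_reference_table("positive")
  expect_equal(nrow(pos), 26L)
  expect_true(all(pos$p < 0.05))

  empty <- rank_table(neg[0, ])
  expect_equal(empty$n_significant, 0L)
})

test_that("full study driver aggregates counts into ranked tables", {
  at <- synth_atlas(dim = c(12, 12, 4), n_regions = 4)
  des <- bold_design(n_acquisitions = 60, baseline_window = c(1, 20),
                     response_window = c(31, 60),
                     groups = data.frame(label = c("vehicle", "3mg"),
                                         dose = c(0, 3), n_subjects = c(3, 3)),
                     seed = 5)
  eff <- list(region_effect_spec(2, c(`3mg` = -3)))
  sim <- generate_bold(des, at, eff, noise_sd = 0.5)
  cfg <- run_config(n_acquisitions = 60, baseline_window = c(1, 20),
                    response_window = c(31, 60))
  res <- run_activation_study(sim$subjects, at, cfg)
  neg <- res$negative
  expect_equal(nrow(neg), 4L)
  r2 <- neg[neg$region_id == 2, ]
  expect_gt(r2$mean_3mg, r2$mean_vehicle)
  expect_lt(r2$p, 0.2)
  expect_true(all(c("H", "p", "omega_sq") %in% names(neg)))
})
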
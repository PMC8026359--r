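test_that("pearson matches hand computations and the formula oracle", {
  expect_equal(pearson(1:4, c(2, 4, 6, 8))$r, 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 4))$r, 0.5) # hand: cov 0.5, sds 1, 1

  set.seed(30)
  for (k in 1:10) {
    x <- rnorm(50); y <- 0.4 * x + rnorm(50)
    got <- pearson(x, y)
    want <- oracle_pearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }

  expect_error(pearson(c(1, 1, 1), 1:3), "variance")
  expect_error(pearson(1:2, 2:3), ">= 3")
})

test_that("pearson is invariant under separate affine transforms", {
  set.seed(31)
  x <- rnorm(25); y <- rnorm(25)
  r0 <- pearson(x, y)$r
  expect_equal(pearson(2 * x + 3, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson(x, -4 * y + 1)$r, -r0, tolerance = 1e-12)
})

test_that("welch and paired t follow the definitions", {
  w <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(w$dof, 4)

  set.seed(32)
  for (k in 1:10) {
    a <- rnorm(12); b <- rnorm(15, 0.5, 2)
    got <- welch_t(a, b)
    want <- oracle_welch(a, b)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
    expect_equal(got$dof, want$dof, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }

  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)), "zero-variance")
  p <- paired_t(c(2, 4, 6, 7), c(1, 2, 3, 5))
  expect_equal(p$dof, 3)
  expect_equal(p$kind, "paired")
})

test_that("welch reduces to the pooled t for equal variances and sizes", {
  set.seed(33)
  a <- rnorm(20); b <- rnorm(20)
  b <- (b - mean(b)) / sd(b) * sd(a) + mean(b) # force equal sample variance
  w <- welch_t(a, b)
  pooled <- t.test(a, b, var.equal = TRUE)
  expect_equal(w$statistic, unname(pooled$statistic), tolerance = 1e-12)
  expect_equal(w$dof, unname(pooled$parameter), tolerance = 1e-12)
})

test_that("a published group contrast is reproduced from printed summaries", {
  # caudal vs rostral hotspot-group latency, means +/- SEM with n = 10 vs 14:
  # SD = SEM * sqrt(n); same sign and rejection as the printed t(20.9) = -2.952
  w <- welch_t_summary(21.7, 0.4 * sqrt(10), 10, 23.3, 0.4 * sqrt(14), 14)
  expect_equal(w$statistic, -2.83, tolerance = 0.01)
  expect_lt(w$statistic, 0)
  expect_lt(w$p, 0.05)
  expect_gt(w$dof, 19)
})

test_that("bonferroni caps at one and honours the family size", {
  expect_equal(bonferroni(c(0.01, 0.03), 2), c(0.02, 0.06))
  expect_equal(bonferroni(0.6, 2), 1)
  expect_equal(bonferroni(0.2, 1), 0.2) # m = 1 identity
  expect_error(bonferroni(c(0.1, 0.2), 1), "family size")
})

test_that("the battery has the documented fixed layout and families", {
  coh <- simulate_cohort(generator_config(seed = 5))
  b <- run_correlation_battery(coh$table)
  expect_equal(nrow(b), 2 + 6 + 12 + 4)
  expect_equal(as.integer(table(b$set)[c("rostrocaudal", "structure_function",
                                         "structure_function_subroi",
                                         "thickness_curvature")]),
               c(2L, 6L, 12L, 4L))
  expect_true(all(b$p_adjusted >= b$p, na.rm = TRUE))
  # R1 rows run on the n with valid R1 only
  expect_equal(unique(b$n[b$x == "r1_mean"]), 20L)
  expect_equal(unique(b$n[b$set == "rostrocaudal"]), 24L)
})

test_that("a noise-free cohort yields perfect correlations where the model is linear", {
  cfg <- generator_config(
    n_subjects = 20, n_r1_missing = 0, seed = 9,
    rho_y_latency = 1, latency_resid_sd = 0, rho_r1_rostrality = 1,
    rho_r1_bold = 1, rho_r1_bold_index = 1, rho_r1_cv = -1,
    rho_r1_cv_index = -1, muscle_y_jitter_sd = 0, mep_amp_between_cv = 0,
    cv_mean = 0.5, cv_between_sd = 0.05, cv_floor = 1e-4)
  b <- run_correlation_battery(simulate_cohort(cfg)$table)
  pick <- function(x, y) b$r[b$x == x & b$y == y]
  # linear couplings are exact
  expect_equal(pick("fdi_hotspot_y", "fdi_latency"), 1, tolerance = 1e-9)
  expect_equal(pick("adm_hotspot_y", "adm_latency"), 1, tolerance = 1e-9)
  expect_equal(pick("r1_mean", "bold_little"), 1, tolerance = 1e-9)
  expect_equal(pick("r1_mean", "bold_index"), 1, tolerance = 1e-9)
  expect_equal(pick("r1_mean", "cv_little"), -1, tolerance = 1e-9)
  expect_equal(pick("r1_mean", "cv_index"), -1, tolerance = 1e-9)
  # the product index is a monotone but nonlinear function of the trait
  expect_gt(pick("r1_mean", "fdi_rostrality"), 0.9)
  expect_gt(pick("r1_mean", "adm_rostrality"), 0.9)
})

test_that("a constant column degrades only its own battery rows", {
  coh <- simulate_cohort(generator_config(seed = 6))
  tab <- coh$table
  tab$bold_little <- 1.3
  b <- run_correlation_battery(tab)
  bad <- b[b$y == "bold_little", ]
  expect_true(all(is.na(bad$r)))
  expect_true(all(!is.na(bad$error)))
  expect_true(all(is.finite(b$r[b$y == "bold_index"])))
})

test_that("ROI contrasts and group tests run on simulated cohorts", {
  coh <- simulate_cohort(generator_config(seed = 7))
  rc <- roi_contrasts(coh$table)
  expect_equal(sort(rc$measure), sort(c("r1", "thickness", "curvature", "bold")))
  expect_true(all(rc$p_adjusted >= rc$p))
  # the myelin gradient: caudal R1 above rostral R1
  expect_gt(rc$mean_caudal[rc$measure == "r1"], rc$mean_rostral[rc$measure == "r1"])
  expect_lt(rc$p[rc$measure == "r1"], 0.001)

  gt <- group_tests(coh$table)
  expect_true("fdi_latency" %in% gt$measure)
  # rostral hotspots sit more anteriorly by construction
  y <- gt[gt$measure == "fdi_hotspot_y", ]
  expect_gt(y$mean_rostral, y$mean_caudal)
})
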
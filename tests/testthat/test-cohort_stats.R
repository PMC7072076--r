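test_that("Mann-Whitney U agrees with full enumeration on small samples", {
  # fully separated 3 vs 3: U = 0, exact two-sided p = 0.1
  res <- mw_u_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  expect_true(res$exact)

  # all 4-vs-5 configurations of ranks 1..9
  combos <- combn(9, 4)
  for (j in seq_len(ncol(combos))) {
    x <- combos[, j]
    y <- setdiff(1:9, x)
    res <- mw_u_test(x, y)
    oracle <- mw_enum_oracle(x, y)
    expect_equal(res$U, oracle$U)
    expect_equal(res$p, oracle$p, tolerance = 1e-12)
  }

  # identical samples: p ~ 1 (ties force the corrected approximation)
  same <- mw_u_test(rep(1:3, 2), rep(1:3, 2))
  expect_gte(same$p, 0.99)
})

test_that("Fisher and Freeman-Halton p-values equal enumeration oracles", {
  tabs <- list(
    matrix(c(5, 5, 4, 1), 2),     # the sex-by-outcome baseline table
    matrix(c(2, 2, 3, 3), 2),     # proportional: p = 1
    matrix(c(2, 1, 1, 2), 2),
    matrix(c(1, 3, 2, 1), 2),
    matrix(c(4, 0, 1, 5), 2)
  )
  for (tab in tabs) {
    expect_equal(baseline_tests(tab)$p, fisher2x2_enum_oracle(tab),
                 tolerance = 1e-10)
  }
  expect_equal(baseline_tests(matrix(c(2, 2, 3, 3), 2))$p, 1)

  tabs2xk <- list(
    matrix(c(3, 0, 1, 2, 0, 3), 2),           # 2x3, N = 9
    matrix(c(2, 1, 1, 2, 2, 1, 1, 2), 2),     # 2x4, N = 12
    matrix(c(1, 2, 2, 1, 3, 1), 2)
  )
  for (tab in tabs2xk) {
    expect_equal(baseline_tests(tab)$p, freeman_halton_enum_oracle(tab),
                 tolerance = 1e-10)
  }

  expect_error(baseline_tests(matrix(c(0, 0, 3, 2), 2)), "margin")
})

test_that("reference band is the t-based CI of the control mean", {
  expect_equal(unclass(reference_band(rep(7, 5)))[c("lower", "upper")],
               list(lower = 7, upper = 7))
  set.seed(14)
  v <- rnorm(10, 5, 2)
  band <- reference_band(v)
  ci <- t.test(v)$conf.int  # independent route to the same interval
  expect_equal(band$lower, ci[1], tolerance = 1e-10)
  expect_equal(band$upper, ci[2], tolerance = 1e-10)
  expect_error(reference_band(3), "2 controls")

  expect_equal(band_position(band$upper + 1, band), "above")
  expect_equal(band_position(band$mean, band), "within")
  expect_equal(band_position(band$lower - 1, band), "below")
})

test_that("subset ANOVA matches the between/within mean-square oracle", {
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- subset_anova(vals, grp)
  # loop oracle: textbook decomposition
  gm <- mean(vals)
  ssb <- ssw <- 0
  for (g in unique(grp)) {
    v <- vals[grp == g]
    ssb <- ssb + length(v) * (mean(v) - gm)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(res$F, f_oracle, tolerance = 1e-12)
  expect_equal(res$p, pf(f_oracle, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)

  # identical groups with variance: F from oracle, Tukey p ~ 1
  vals2 <- rep(c(1, 2, 3), 3)
  res2 <- subset_anova(vals2, rep(c("a", "b", "c"), each = 3))
  expect_equal(res2$F, 0, tolerance = 1e-12)
  expect_true(all(res2$tukey$p_adj > 0.999))

  # distinct means, zero within-group variance: p floored at 0, flagged
  res3 <- subset_anova(rep(c(1, 2, 3), each = 3),
                       rep(c("a", "b", "c"), each = 3))
  expect_true(res3$p_floor)
  expect_equal(res3$p, 0)

  expect_error(subset_anova(1:5, c("a", "a", "b", "b", "c")), "n >= 2")
})

test_that("Spearman and Friedman behave on canonical inputs", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(spearman_cor(x, 2 * x + 1)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  expect_true(spearman_cor(x, rep(3, 5))$undefined)

  mat <- matrix(rep(c(2, 5, 1, 4, 3), 3), ncol = 3)
  res <- friedman_conditions(mat)
  expect_equal(res$statistic, 0)
  expect_error(friedman_conditions(mat[1, , drop = FALSE]), ">= 2")
})

test_that("normality screen is deterministic and flags a uniform sample", {
  set.seed(15)
  u <- runif(50)
  g <- rnorm(50)
  r1 <- normality_screen(u)
  r2 <- normality_screen(u)
  expect_identical(r1, r2)
  expect_lt(r1$p, 0.05)
  expect_gt(normality_screen(g)$p, 0.05)
})

test_that("per-timepoint test flags an empty group instead of testing", {
  d <- simulate_metric_cohort(delta = 1, n_per_group = 4, seed = 16)
  res <- per_timepoint_test(d, "mean_acid_ratio", day = 0)
  expect_false(res$missing)
  expect_true(res$p >= 0 && res$p <= 1)
  d2 <- d[!(d$group == "infection" & d$day == 3), ]
  res2 <- per_timepoint_test(d2, "mean_acid_ratio", day = 3)
  expect_true(res2$missing)
  expect_true(is.na(res2$p))
})

test_that("all reported p-values lie in [0, 1]", {
  for (s in 1:5) {
    set.seed(700 + s)
    x <- rnorm(6)
    y <- rnorm(5, 0.5)
    expect_true(mw_u_test(x, y)$p >= 0 && mw_u_test(x, y)$p <= 1)
    tab <- matrix(rpois(4, 3) + 1, 2)
    expect_true(baseline_tests(tab)$p >= 0 && baseline_tests(tab)$p <= 1)
    expect_true(spearman_cor(x, rnorm(6))$p >= 0)
  }
})
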
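test_that("positivity cut from a negative reference is its 99.5th percentile", {
  # constant reference: percentile of a constant is that constant
  ref <- make_table(100, PF520 = 42)
  tab <- make_table(10)
  res <- pf520_positive_threshold(tab, rep(TRUE, 10),
                                  negative_reference = ref)
  expect_equal(res$cut, asinh(42 / 150))
  expect_equal(res$method, "reference_quantile")

  # lognormal reference: cut equals the empirical percentile exactly
  set.seed(8)
  v <- rlnorm(500, 3, 0.4)
  ref2 <- make_table(500, PF520 = v)
  res2 <- pf520_positive_threshold(tab, rep(TRUE, 10),
                                   negative_reference = ref2)
  expect_equal(res2$cut, unname(quantile(asinh(v / 150), 0.995)))

  # empty reference falls back to the density route with a warning
  empty <- make_table(0)
  tab2 <- make_table(2000, PF520 = c(rlnorm(1000, 3, 0.3),
                                     rlnorm(1000, 6.2, 0.3)))
  expect_warning(
    res3 <- pf520_positive_threshold(tab2, rep(TRUE, 2000),
                                     negative_reference = empty),
    "falling back")
  expect_true(res3$method %in% c("valley", "quantile"))
})

test_that("valley-based PF520 cut lands between generator modes", {
  set.seed(9)
  neg <- rlnorm(3000, 3, 0.4)
  pos <- rlnorm(3000, 6.2, 0.35)
  tab <- make_table(6000, PF520 = c(neg, pos))
  res <- pf520_positive_threshold(tab, rep(TRUE, 6000))
  expect_equal(res$method, "valley")
  # the cut separates the two generating modes
  expect_gt(res$cut, asinh(exp(3 + 3 * 0.4) / 150))
  expect_lt(res$cut, asinh(exp(6.2 - 3 * 0.35) / 150))
})

test_that("phagocytosis fraction is the percentage above the cut", {
  tab <- make_table(10, PF520 = c(rep(10, 5), rep(1000, 5)))
  flags <- rep(TRUE, 10)
  cut <- asinh(100 / 150)
  expect_equal(phagocytosis_fraction(tab, flags, cut)$pct, 50)
  expect_equal(phagocytosis_fraction(tab, flags, asinh(2000 / 150))$pct, 0)
  res0 <- phagocytosis_fraction(tab, rep(FALSE, 10), cut)
  expect_true(res0$undefined)
  expect_true(is.na(res0$pct))
})

test_that("phagocytosis under Poisson uptake matches the zero-class formula", {
  cfg <- synth_config(seed = 71, n_events = 18000, lambda60 = 1.2)
  sim <- simulate_sample(cfg, meta = list(incubation_min = 60,
                                          temperature_c = 30))
  truth_neu <- sim$truth$population == "granulocyte" &
    !sim$truth$is_eosinophil
  thr <- pf520_positive_threshold(sim$table, truth_neu)
  res <- phagocytosis_fraction(sim$table, truth_neu, thr$cut)
  p0 <- 1 - exp(-1.2)
  n <- res$n_neutrophils
  half <- qnorm(0.995) * sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(res$pct / 100 - p0), half)
})

test_that("mean acidification ratio has its closed forms", {
  # proportional channels: ratio exactly 2
  set.seed(10)
  pf <- rlnorm(200, 6, 0.3)
  tab <- make_table(200, PF520 = pf, PHRODO = 2 * pf)
  fm <- acidification_metrics(tab, rep(TRUE, 200), cut = 0)
  expect_identical(fm$mean_acid_ratio, 2)

  # 50 listed pairs: mean of elementwise ratios equals a loop oracle
  set.seed(11)
  pf2 <- rlnorm(50, 6, 0.4)
  ph2 <- rlnorm(50, 5.5, 0.4)
  tab2 <- make_table(50, PF520 = pf2, PHRODO = ph2)
  fm2 <- acidification_metrics(tab2, rep(TRUE, 50), cut = 0)
  acc <- 0
  for (i in 1:50) acc <- acc + ph2[i] / pf2[i]
  expect_equal(fm2$mean_acid_ratio, acc / 50, tolerance = 1e-12)
  expect_equal(fm2$mfi_pf520, mean(pf2))
  expect_equal(fm2$mfi_phrodo, mean(ph2))

  # zero positive cells: flagged undefined, no numeric output
  tab3 <- make_table(20, PF520 = 1)
  fm3 <- acidification_metrics(tab3, rep(TRUE, 20), cut = asinh(10))
  expect_true(fm3$undefined)
  expect_true(is.na(fm3$mean_acid_ratio))
  expect_true(is.na(fm3$mfi_pf520))
})

test_that("ratio is invariant under common rescaling of both channels", {
  set.seed(12)
  pf <- rlnorm(300, 6, 0.3)
  ph <- rlnorm(300, 5.6, 0.3)
  tab <- make_table(300, PF520 = pf, PHRODO = ph)
  base <- acidification_metrics(tab, rep(TRUE, 300), cut = 0)
  for (s in c(0.5, 3, 10)) {
    tab_s <- make_table(300, PF520 = s * pf, PHRODO = s * ph)
    scaled <- acidification_metrics(tab_s, rep(TRUE, 300), cut = 0)
    expect_equal(scaled$mean_acid_ratio, base$mean_acid_ratio,
                 tolerance = 1e-12)
  }
})

test_that("phagocytosis % is invariant under monotone PF520 transforms", {
  set.seed(13)
  pf <- rlnorm(500, 5, 1)
  tab <- make_table(500, PF520 = pf)
  cut_raw <- 150  # raw-units cut
  f1 <- phagocytosis_fraction(tab, rep(TRUE, 500), asinh(cut_raw / 150))
  mono <- function(x) x^2 + 3 * x  # strictly increasing on x >= 0
  tab2 <- make_table(500, PF520 = mono(pf))
  f2 <- phagocytosis_fraction(tab2, rep(TRUE, 500),
                              asinh(mono(cut_raw) / 150))
  expect_equal(f1$pct, f2$pct)
})

test_that("kinetics series orders time points and flags gaps", {
  mk <- function(t) acidification_metrics(
    make_table(10, PF520 = 500, PHRODO = 250,
               meta = list(incubation_min = t)),
    rep(TRUE, 10), cut = 0)
  shuffled <- lapply(c(40, 10, 60, 20), mk)
  kc <- kinetics_curve(shuffled)
  expect_equal(kc$times, c(10, 20, 40, 60))
  expect_equal(length(kc$missing), 0)

  single <- kinetics_curve(list(mk(20)))
  expect_equal(single$times, 20)
  expect_equal(sort(single$missing), c(10, 40, 60))

  expect_error(kinetics_curve(list(mk(10), mk(10))), "duplicate")
})

test_that("mean phagocytosis kinetics rise with incubation time", {
  # uptake rate increases in t, so the seed-averaged curve is monotone
  fracs <- matrix(NA_real_, nrow = 20, ncol = 4)
  times <- c(10, 20, 40, 60)
  for (s in 1:20) {
    for (j in 1:4) {
      cfg <- synth_config(seed = 500 + s, n_events = 1500)
      sim <- simulate_sample(cfg, meta = list(incubation_min = times[j],
                                              seed = 500 + s * 17 + j))
      neu <- sim$truth$population == "granulocyte" & !sim$truth$is_eosinophil
      fracs[s, j] <- mean(sim$truth$k[neu] > 0)
    }
  }
  curve <- colMeans(fracs)
  expect_true(all(diff(curve) > 0))
})
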
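test_that("identical seeds give identical samples", {
  s1 <- simulate_sample(synth_config(seed = 123, n_events = 2000))
  s2 <- simulate_sample(synth_config(seed = 123, n_events = 2000))
  expect_identical(s1$table$exprs, s2$table$exprs)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_sample(synth_config(seed = 124, n_events = 2000))
  expect_false(identical(s1$table$exprs, s3$table$exprs))
})

test_that("invalid configurations fail validation before sampling", {
  expect_error(synth_config(eosinophil_frac = 1.2), "eosinophil")
  expect_error(synth_config(ph_slope = -1), "decreasing")
  bad_pop <- data.frame(name = "granulocyte", fraction = 0.5,
                        fsc_mean = 1, fsc_sd = 1, ssc_mean = 1, ssc_sd = 1)
  expect_error(synth_config(populations = bad_pop), "sum to 1")
})

test_that("particle-carrying fraction follows the Poisson zero class", {
  cfg <- synth_config(seed = 80, n_events = 18000, lambda60 = 1.2)
  sim <- simulate_sample(cfg)
  neu <- sim$truth$population == "granulocyte" & !sim$truth$is_eosinophil
  frac <- mean(sim$truth$k[neu] > 0)
  p0 <- 1 - exp(-1.2)
  half <- qnorm(0.995) * sqrt(p0 * (1 - p0) / sum(neu))
  expect_lt(abs(frac - p0), half)
})

test_that("lower phagosomal pH means brighter pHrodo relative to PF520", {
  base <- synth_config(seed = 81, n_events = 6000)
  tweak <- function(ph) {
    cfg <- base
    cfg$ph_end_table$ph_end <- ph
    cfg
  }
  ratio_at <- function(cfg) {
    sim <- simulate_sample(cfg)
    k <- sim$truth$k
    ex <- sim$table$exprs
    mean(ex[k > 0, "PHRODO"] / ex[k > 0, "PF520"])
  }
  expect_gt(ratio_at(tweak(6.0)), ratio_at(tweak(7.4)))
  # and the configured response curve itself is strictly decreasing
  grid <- seq(4.5, 7.4, by = 0.1)
  expect_true(all(diff(phrodo_response(grid, base)) < 0))
})

test_that("cohort simulation writes one sample per patient-day-time", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(seed = 82, n_events = 150)
  coh <- simulate_cohort(cfg, n_infection = 2, n_no_infection = 2,
                         n_controls = 1, days = c(0, 3), times = 60,
                         dir = dir)
  # 4 patients x 2 days + 1 control x 1 day = 9 FCS files
  fcs <- list.files(dir, pattern = "\\.fcs$")
  expect_equal(length(fcs), 9)
  expect_equal(nrow(coh$sheet), 9)
  expect_true(file.exists(file.path(dir, "sample_sheet.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  # files round trip through the FCS layer
  back <- read_fcs(file.path(dir, coh$sheet$fcs_path[1]))
  expect_equal(n_events(back), 150)
})

test_that("pipeline estimates converge to configured truth with event count", {
  sizes <- c(1000, 4000, 16000)
  err <- vapply(sizes, function(n) {
    sim <- simulate_sample(synth_config(seed = 83, n_events = n))
    g <- gate_sample(sim$table)
    truth_neu <- sim$truth$population == "granulocyte" &
      !sim$truth$is_eosinophil
    abs(sum(g$neutrophil) / sum(truth_neu) - 1)
  }, 1.0)
  expect_lt(err[3], 0.02)
  expect_lte(err[3], err[1] + 0.005)
})

test_that("uptake rises with temperature while acidification is stable", {
  cfg <- synth_config(seed = 84, n_events = 8000)
  temps <- seq(0, 37, length.out = 8)
  lam <- lambda_uptake(60, temps, cfg)
  expect_true(all(diff(lam) > 0))

  stats_at <- function(temp) {
    sim <- simulate_sample(cfg, meta = list(temperature_c = temp,
                                            seed = 84 + round(temp)))
    k <- sim$truth$k
    ex <- sim$table$exprs
    c(frac = mean(k[sim$truth$population == "granulocyte" &
                      !sim$truth$is_eosinophil] > 0),
      ratio = mean(ex[k > 0, "PHRODO"] / ex[k > 0, "PF520"]))
  }
  s0 <- stats_at(0); s25 <- stats_at(25); s37 <- stats_at(37)
  expect_lt(s0[["frac"]], s25[["frac"]])
  expect_lt(s25[["frac"]], s37[["frac"]])
  expect_lt(abs(s37[["ratio"]] / s0[["ratio"]] - 1), 0.10)
})
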
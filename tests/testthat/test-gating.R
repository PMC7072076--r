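test_that("scatter mixture recovers three well-separated clusters", {
  sim <- simulate_sample(three_cluster_config(seed = 21, n_events = 10000))
  res <- gate_granulocytes(sim$table)
  agree <- mean(as.character(res$population) == sim$truth$population)
  expect_gte(agree, 0.99)
})

test_that("zero-event tables gate to empty labels without error", {
  sim <- simulate_sample(synth_config(seed = 1, n_events = 0))
  g <- gate_sample(sim$table)
  expect_equal(length(g$population), 0)
  expect_equal(length(g$neutrophil), 0)
  expect_true(all(is.na(g$percentages)))
})

test_that("too few events raise a gating error", {
  sim <- simulate_sample(synth_config(seed = 2, n_events = 50))
  expect_error(gate_granulocytes(sim$table), "minimum")
})

test_that("manual polygon gates everything inside as granulocyte", {
  tab <- make_table(50, FSC = runif(50, 10, 20), SSC = runif(50, 10, 20))
  poly <- cbind(c(0, 30, 30, 0), c(0, 0, 30, 30))
  cfg <- gate_config(mode = "manual", polygon = poly,
                     cd16_positive_cut = 0, cd16_bright_cut = 0,
                     cd62l_bright_cut = 0)
  res <- gate_granulocytes(tab, cfg)
  expect_true(all(res$population == "granulocyte"))
})

test_that("CD16 gate excludes the eosinophil mode at <= 1% error", {
  sim <- simulate_sample(synth_config(seed = 31, n_events = 10000))
  pop <- factor(sim$truth$population, levels = phagoflow:::POPULATION_LEVELS)
  res <- gate_neutrophils(sim$table, pop)
  truth_neu <- sim$truth$population == "granulocyte" &
    !sim$truth$is_eosinophil
  gran <- sim$truth$population == "granulocyte"
  mis <- mean(res$neutrophil[gran] != truth_neu[gran])
  expect_lte(mis, 0.01)
  expect_equal(res$method, "valley")
})

test_that("unimodal CD16 falls back to the quantile cut", {
  set.seed(5)
  n <- 2000
  tab <- make_table(n, CD16 = rlnorm(n, 6.8, 0.15))
  pop <- factor(rep("granulocyte", n),
                levels = phagoflow:::POPULATION_LEVELS)
  cfg <- gate_config(fallback_quantile = 0.01)
  res <- gate_neutrophils(tab, pop, cfg)
  expect_equal(res$method, "quantile")
  expect_equal(mean(res$neutrophil), 0.99, tolerance = 0.005)
  # empty granulocyte set errors
  none <- factor(rep("other", n), levels = phagoflow:::POPULATION_LEVELS)
  expect_error(gate_neutrophils(tab, none), "granulocyte")
})

test_that("subset percentages recover generator proportions within 1 pp", {
  sim <- simulate_sample(synth_config(seed = 41, n_events = 36000))
  g <- gate_sample(sim$table)
  expect_gte(sum(g$neutrophil), 19000)
  truth_sub <- sim$truth$subset[sim$truth$population == "granulocyte" &
                                  !sim$truth$is_eosinophil]
  truth_pct <- 100 * table(factor(truth_sub,
    levels = phagoflow:::SUBSET_LEVELS[1:3])) / length(truth_sub)
  est <- g$percentages[1:3]
  expect_true(all(abs(est - as.numeric(truth_pct)) <= 1))
})

test_that("zero neutrophils yield flagged-undefined percentages, not zero", {
  tab <- make_table(100)
  res <- classify_subsets(tab, rep(FALSE, 100))
  expect_true(res$undefined)
  expect_true(all(is.na(res$percentages)))
})

test_that("events exactly on a cut are assigned to the bright side", {
  cfg <- gate_config(mode = "manual",
                     polygon = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                     cd16_positive_cut = 0,
                     cd16_bright_cut = asinh(300 / 150),
                     cd62l_bright_cut = asinh(300 / 150))
  tab <- make_table(4, CD16 = c(300, 300, 299.9, 300),
                    CD62L = c(300, 299.9, 300, 300))
  res <- classify_subsets(tab, rep(TRUE, 4), cfg)
  labs <- as.character(res$subset)
  expect_equal(labs[1], "cd16bright_cd62lbright")  # both exactly on cut
  expect_equal(labs[2], "cd16bright_cd62ldim")
  expect_equal(labs[3], "cd16dim_cd62lbright")
})

test_that("gating is deterministic and replays from emitted thresholds", {
  sim <- simulate_sample(synth_config(seed = 51, n_events = 6000))
  g1 <- gate_sample(sim$table)
  g2 <- gate_sample(sim$table)
  expect_identical(g1$population, g2$population)
  expect_identical(g1$neutrophil, g2$neutrophil)
  replay <- gate_sample(sim$table, thresholds = g1$thresholds)
  expect_identical(as.character(replay$population),
                   as.character(g1$population))
  expect_identical(replay$neutrophil, g1$neutrophil)
  expect_identical(as.character(replay$subset), as.character(g1$subset))
  expect_equal(replay$percentages, g1$percentages)
})

test_that("population labels partition events; subsets partition neutrophils", {
  for (seed in c(61, 62)) {
    sim <- simulate_sample(synth_config(seed = seed, n_events = 4000))
    g <- gate_sample(sim$table)
    expect_false(anyNA(g$population))
    expect_true(all(g$neutrophil[g$neutrophil] %in% TRUE))
    expect_true(all(as.character(g$population)[g$neutrophil] ==
                      "granulocyte"))
    expect_false(anyNA(g$subset[g$neutrophil]))
    expect_true(all(is.na(g$subset[!g$neutrophil])))
    expect_lte(sum(g$percentages[1:3]), 100 + 1e-9)
  }
})
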
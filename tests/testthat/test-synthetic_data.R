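test_that("simulation is bit-identical under a fixed seed and differs across seeds", {
  cfg7 <- two_type_config(n = 60, seed = 7)
  m1 <- simulate_counts(cfg7)
  m2 <- simulate_counts(cfg7)
  expect_identical(m1, m2)
  m3 <- simulate_counts(two_type_config(n = 60, seed = 8))
  expect_false(identical(m1$counts, m3$counts))

  g1 <- simulate_growth(growth_scenario(seed = 7))
  g2 <- simulate_growth(growth_scenario(seed = 7))
  expect_identical(g1, g2)
  expect_false(identical(g1, simulate_growth(growth_scenario(seed = 8))))
})

test_that("config validation names the offender", {
  props <- list(control = c(M2 = 0.7, CD8_T = 0.4),
                treated = c(M2 = 0.6, CD8_T = 0.4))
  expect_error(scenario_config(cell_type_proportions = props), "sum")
  expect_error(scenario_config(mu_high = 0.1, mu_low = 0.3), "mu_high")
  expect_error(scenario_config(dispersion = 0), "dispersion")
  expect_error(
    simulate_counts(two_type_config(
      treatment_effects = data.frame(cell_type = "Platelet", gene = "Gzmb",
                                     fold = 2))),
    "Platelet")
  expect_error(
    simulate_counts(two_type_config(
      treatment_effects = data.frame(cell_type = "CD8_T", gene = "NoSuch",
                                     fold = 2))),
    "NoSuch")
})

test_that("mu_low = 0 makes every non-positive panel gene exactly 0", {
  cfg <- scenario_config(
    n_cells_per_condition = 50,
    cell_type_proportions = list(control = c(M2 = 0.5, CD8_T = 0.5),
                                 treated = c(M2 = 0.5, CD8_T = 0.5)),
    mu_low = 0, extra_means = NULL, treatment_effects = NULL,
    n_background_genes = 0, n_program_genes = 0, n_mito_genes = 0,
    seed = 2)
  m <- simulate_counts(cfg)
  panel <- default_marker_panel()
  for (ty in c("M2", "CD8_T")) {
    neg <- colnames(panel)[unclass(panel)[ty, ] != 1L]
    expect_true(all(m$counts[m$true_type == ty, neg] == 0))
  }
})

test_that("planted type proportions are recovered within 3 binomial SD", {
  cfg <- two_type_config(n = 5000, seed = 11)
  m <- simulate_counts(cfg)
  frac <- mean(m$true_type == "M2")
  sd3 <- 3 * sqrt(0.6 * 0.4 / length(m$true_type))
  expect_lt(abs(frac - 0.6), sd3)
})

test_that("+1 marker mean converges to mu_high and folds are recovered", {
  cfg <- scenario_config(
    n_cells_per_condition = 2500,
    cell_type_proportions = list(control = c(CD8_T = 1),
                                 treated = c(CD8_T = 1)),
    extra_means = data.frame(cell_type = "CD8_T", gene = "Gzmb", mean = 2),
    treatment_effects = data.frame(cell_type = "CD8_T", gene = "Gzmb",
                                   fold = 2),
    n_background_genes = 10, n_program_genes = 0, n_mito_genes = 0,
    seed = 4)
  m <- simulate_counts(cfg)
  # 5000 cells total express Cd8a at mu_high = 8 (library factors mean 1)
  expect_lt(abs(mean(m$counts[, "Cd8a"]) / cfg$mu_high - 1), 0.05)
  # planted 2x fold recovered from the treated/control mean ratio
  ratio <- mean(m$counts[m$condition == "treated", "Gzmb"]) /
    mean(m$counts[m$condition == "control", "Gzmb"])
  expect_lt(abs(ratio / 2 - 1), 0.10)
})

test_that("noise-free growth follows the exponential law exactly", {
  sc <- growth_scenario(n_mice_per_group = 3, noise_cv = 0,
                        growth_rate_control = 0.1,
                        growth_rate_treated = 0.1, seed = 1)
  g <- simulate_growth(sc)
  mc <- tapply(g$volume_mm3[g$group == "control"],
               g$day[g$group == "control"], mean)
  mt <- tapply(g$volume_mm3[g$group == "treated"],
               g$day[g$group == "treated"], mean)
  expect_equal(unname(mc), unname(mt), tolerance = 1e-12)

  sc2 <- growth_scenario(noise_cv = 0, seed = 1)
  g2 <- simulate_growth(sc2)
  ratio <- 1 - endpoint_reduction(g2)
  d_final <- max(sc2$days)
  expect_equal(ratio,
               exp((sc2$growth_rate_treated - sc2$growth_rate_control) *
                     d_final),
               tolerance = 1e-9)
  expect_equal(ratio, 0.34, tolerance = 1e-9) # default rates plant 66%
})

test_that("growth volumes honor the calliper formula and aspect", {
  g <- simulate_growth(growth_scenario(n_mice_per_group = 2, seed = 3))
  expect_equal(g$volume_mm3, g$width_mm^2 * g$length_mm / 2,
               tolerance = 1e-9)
  expect_equal(g$width_mm / g$length_mm,
               rep(0.8, nrow(g)), tolerance = 1e-9)
  expect_error(growth_scenario(days = c(0, 2, 2)), "increasing")
  expect_error(growth_scenario(n_mice_per_group = 1), "2 mice")
  expect_error(growth_scenario(v0_mean = 0), "v0_mean")
})
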
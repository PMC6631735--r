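test_that("rr_shift matches the log-linear closed form", {
  a <- assoc("fruit", "chd", 0.93, 106)
  expect_identical(rr_shift(a, 250, 250), 1)
  expect_equal(rr_shift(a, 250, 356), 0.93, tolerance = 1e-12)
  expect_equal(rr_shift(a, 356, 250), 1 / 0.93, tolerance = 1e-12)
  expect_equal(rr_shift(a, 250, 250 + 53), 0.93^0.5, tolerance = 1e-12)

  # degenerate distributions collapse the integrated method onto mean_shift
  v <- rr_shift(a, 250, 356, sd_base = 1e-6, sd_cf = 1e-6,
                method = "distribution_integrated")
  expect_equal(v, 0.93, tolerance = 1e-6)
  expect_identical(rr_shift(a, 250, 250, 1e-6, 1e-6,
                            method = "distribution_integrated"), 1)

  huge <- assoc("fruit", "chd", rr = 1e-300, unit = 1e-6)
  expect_error(rr_shift(huge, 0, 1e6), "non-finite")
})

test_that("integrated rr_shift agrees with a Monte Carlo expectation oracle", {
  # randomized association/distribution instances; E[rr^(X/unit)] by draws
  set.seed(2024)
  for (i in 1:20) {
    rr <- runif(1, 0.7, 1.3)
    unit <- runif(1, 1, 150)
    mu_b <- runif(1, 50, 300); sd_b <- runif(1, 5, 80)
    mu_c <- mu_b * runif(1, 0.8, 1.2); sd_c <- sd_b * runif(1, 0.8, 1.2)
    a <- assoc("fruit", "chd", rr, unit)
    got <- rr_shift(a, mu_b, mu_c, sd_b, sd_c, method = "distribution_integrated")
    n <- 1e5
    num <- rr^(rnorm(n, mu_c, sd_c) / unit)
    den <- rr^(rnorm(n, mu_b, sd_b) / unit)
    est <- mean(num) / mean(den)
    # delta-method MC standard error of the ratio
    se <- est * sqrt(var(num) / n / mean(num)^2 + var(den) / n / mean(den)^2)
    expect_lt(abs(got - est), 3 * se)
  }
})

test_that("integrated rr_shift matches the lognormal-moment closed form", {
  # independent algebraic oracle: E[exp(bX)] = exp(b mu + b^2 sd^2 / 2)
  a <- assoc("fruit", "chd", 0.9, 100)
  b <- log(0.9) / 100
  closed <- exp(b * 180 + b^2 * 60^2 / 2) / exp(b * 220 + b^2 * 50^2 / 2)
  expect_equal(rr_shift(a, 220, 180, 50, 60, method = "distribution_integrated"),
               closed, tolerance = 1e-9)
})

test_that("mediated shifts propagate linearly and exponentiate the final RR", {
  a <- assoc("salt", "stroke", rr = 1.02, unit = 1,
             mediation = "salt_sbp", mediation_coeffs = 1.0)
  expect_identical(rr_shift_mediated(a, 8, 8), 1)
  expect_equal(rr_shift_mediated(a, 8, 7), 1.02^-1, tolerance = 1e-12)
  expect_equal(round(rr_shift_mediated(a, 8, 7), 4), 0.9804)

  # doubling both the slope and the log-RR quadruples the log-ratio
  a2 <- assoc("salt", "stroke", rr = 1.02^2, unit = 1,
              mediation = "salt_sbp", mediation_coeffs = 2.0)
  expect_equal(log(rr_shift_mediated(a2, 8, 7)),
               4 * log(rr_shift_mediated(a, 8, 7)), tolerance = 1e-12)

  # multi-step chains compose their slopes
  a3 <- assoc("energy", "chd", rr = 1.05, unit = 1,
              mediation = "energy_bmi", mediation_coeffs = c(0.002, 0.5))
  expect_equal(log(rr_shift_mediated(a3, 2000, 1900)),
               -100 * 0.001 * log(1.05), tolerance = 1e-12)

  expect_error(rr_shift_mediated(assoc("fruit", "chd"), 1, 2), "no mediation")
  expect_error(risk_association("salt", "stroke", 1.02, 1, 1.0, 1.04,
                                mediation = "salt_sbp"), "mediation_coeffs")
})

test_that("run_scenario matches closed-form arithmetic on a single stratum", {
  pop <- tiny_pop(sexes = "male", count = 100000)
  mort <- tiny_mort(pop, causes = "chd", deaths = 1000)
  base <- tiny_diet(sexes = "male", fruit_mean = 250)
  cf <- as.data.frame(base); cf$fruit_mean <- 356
  cf <- diet_distribution(cf)
  res <- run_scenario(pop, mort, base, cf,
                      list(assoc("fruit", "chd", 0.93, 106)))
  expect_equal(res$deaths_cf, 930, tolerance = 1e-12)
  expect_equal(res$averted, 70, tolerance = 1e-12)
  expect_identical(res$averted, res$deaths_base - res$deaths_cf)
})

test_that("associations on one cause combine multiplicatively", {
  pop <- tiny_pop(sexes = "male")
  mort <- tiny_mort(pop, causes = "chd", deaths = 1000)
  base <- tiny_diet(sexes = "male", fruit_mean = 250, veg_mean = 200)
  cf <- as.data.frame(base)
  cf$fruit_mean <- 250 + 106 * log(0.9) / log(0.93)   # ratio exactly 0.9
  cf$veg_mean <- 200 + 106 * log(0.95) / log(0.94)    # ratio exactly 0.95
  cf <- diet_distribution(cf)
  res <- run_scenario(pop, mort, base, cf,
                      list(assoc("fruit", "chd", 0.93, 106),
                           assoc("vegetable", "chd", 0.94, 106)))
  expect_equal(res$deaths_cf / res$deaths_base, 0.855, tolerance = 1e-12)
  # multiplicative decomposition of the log ratio
  expect_equal(log(res$deaths_cf / res$deaths_base), log(0.9) + log(0.95),
               tolerance = 1e-12)
})

test_that("null scenarios, pass-through causes and stratum checks hold", {
  cfg <- small_cfg(seed = 8)
  pop <- generate_population(cfg)
  mort <- generate_mortality(cfg, pop)
  base <- generate_diet(cfg)
  assocs <- read_associations()

  res <- run_scenario(pop, mort, base, base, assocs)
  expect_true(all(res$averted == 0))
  expect_equal(nrow(res), 36 * 7)  # every (stratum, cause) pair covered

  # causes without associations pass through unchanged
  cf <- build_counterfactual(base, read_effect_table()[["NutriScore/mean"]])
  res2 <- run_scenario(pop, mort, base, cf, assocs)
  expect_equal(res2$deaths_cf[res2$cause_id == "other_ncd"],
               res2$deaths_base[res2$cause_id == "other_ncd"])

  half <- population_table(as.data.frame(pop)[pop$sex == "male", ])
  expect_error(run_scenario(half, mort, base, cf, assocs), "stratum mismatch")
})

test_that("direction consistency and scale equivariance hold", {
  cfg <- small_cfg(seed = 10)
  pop <- generate_population(cfg)
  mort <- generate_mortality(cfg, pop)
  base <- generate_diet(cfg)
  # all-beneficial scenario: every association ratio < 1
  cf <- build_counterfactual(base, eff(fruit = 10, vegetable = 10, fibre = 10,
                                       salt = -10, fats = -10, sfa = -10))
  assocs <- beneficial_assocs()
  res <- run_scenario(pop, mort, base, cf, assocs)
  touched <- unique(vapply(assocs, function(a) a$disease, ""))
  with_deaths <- res$cause_id %in% touched & res$deaths_base > 0
  expect_true(all(res$averted[with_deaths] > 0))

  # multiplying deaths by k multiplies every averted count by k
  mort5 <- as.data.frame(mort); mort5$deaths <- mort5$deaths * 5
  res5 <- run_scenario(pop, mortality_table(mort5), base, cf, assocs)
  expect_equal(res5$averted, 5 * res$averted, tolerance = 1e-12)
})

test_that("aggregation sums strata into cause groups correctly", {
  cfg <- small_cfg(seed = 12)
  pop <- generate_population(cfg)
  mort <- generate_mortality(cfg, pop)
  base <- generate_diet(cfg)
  res <- run_scenario(pop, mort, base, base, read_associations())
  agg0 <- aggregate_averted(res)
  expect_equal(agg0$total, 0)
  expect_true(all(unlist(agg0$per_cause) == 0))

  cf <- build_counterfactual(base, read_effect_table()[["NutriScore/mean"]])
  res <- run_scenario(pop, mort, base, cf, read_associations())
  agg <- aggregate_averted(res)
  expect_equal(agg$total, sum(res$averted), tolerance = 1e-12)
  expect_equal(agg$total, agg$cardiovascular + agg$cancer + agg$other,
               tolerance = 1e-12)
  expect_equal(agg$cancer,
               sum(res$averted[res$cause_id %in% c("lung_cancer", "colorectal_cancer")]),
               tolerance = 1e-12)
  # additivity structure of a published-style summary row: group sums add up
  expect_equal(6189 + 1030 + 461, 7680)

  # permutation invariance
  perm <- res[sample(nrow(res)), ]
  attr(perm, "registry") <- attr(res, "registry")
  agg_p <- aggregate_averted(perm)
  expect_equal(agg_p$total, agg$total, tolerance = 1e-12)
  expect_equal(agg_p$per_cause[names(agg$per_cause)], agg$per_cause)
})
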
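test_that("association resampling is log-normal around the point estimate", {
  a_fixed <- assoc("fruit", "chd", 0.93, 106)  # degenerate CI
  draws <- replicate(20, sample_associations(list(a_fixed), sample.int(1e6, 1))[[1]]$rr)
  expect_true(all(draws == 0.93))

  a <- assoc("fruit", "chd", 0.93, 106, ci_low = 0.88, ci_high = 0.98)
  rrs <- vapply(seq_len(1e5), function(i) {
    sample_associations(list(a), i)[[1]]$rr
  }, numeric(1))
  q <- quantile(rrs, c(0.025, 0.5, 0.975), names = FALSE)
  # the 95% CI is recovered as the 2.5/97.5 empirical percentiles
  expect_lt(abs(q[1] - 0.88), 0.005)
  expect_lt(abs(q[3] - 0.98), 0.005)
  expect_lt(abs(q[2] - 0.93), 0.005)

  expect_identical(sample_associations(list(a), 7L)[[1]]$rr,
                   sample_associations(list(a), 7L)[[1]]$rr)
  bad <- a; bad$ci_high <- 0.80
  expect_error(sample_associations(list(bad), 1), "ci_high < ci_low")
})

test_that("credible summaries collapse, order and reproduce as required", {
  cfg <- small_cfg(seed = 21)
  pop <- generate_population(cfg)
  mort <- generate_mortality(cfg, pop)
  base <- generate_diet(cfg)
  cf <- build_counterfactual(base, read_effect_table()[["NutriScore/mean"]])

  # degenerate CIs: all five percentiles equal the point estimate
  fixed <- list(assoc("fruit", "chd", 0.93, 106),
                assoc("salt", "stroke", 1.04, 1,
                      mediation = "salt_sbp", mediation_coeffs = 1.0))
  cs <- monte_carlo_scenario(pop, mort, base, cf, fixed, n_draws = 50, seed = 5)
  for (p in colnames(cs$percentiles)) {
    expect_equal(cs$percentiles[, p], cs$point, tolerance = 1e-12)
  }

  # null scenario: every percentile exactly zero
  cs0 <- monte_carlo_scenario(pop, mort, base, base, beneficial_assocs(),
                              n_draws = 50, seed = 5)
  expect_true(all(cs0$percentiles == 0))
  expect_true(all(cs0$point == 0))

  # percentile monotonicity on a stochastic run
  cs1 <- monte_carlo_scenario(pop, mort, base, cf, beneficial_assocs(),
                              n_draws = 200, seed = 6)
  for (k in rownames(cs1$percentiles)) {
    expect_false(is.unsorted(cs1$percentiles[k, ]), label = k)
  }

  # reproducible from (seed, n_draws, inputs)
  cs2 <- monte_carlo_scenario(pop, mort, base, cf, beneficial_assocs(),
                              n_draws = 200, seed = 6)
  expect_identical(cs1, cs2)
})

test_that("the median of a log-symmetric toy tracks the point estimate", {
  pop <- tiny_pop(sexes = "male", count = 1e6)
  mort <- tiny_mort(pop, causes = "chd", deaths = 10000)
  base <- tiny_diet(sexes = "male", fruit_mean = 250)
  cf <- as.data.frame(base); cf$fruit_mean <- 356; cf <- diet_distribution(cf)
  a <- assoc("fruit", "chd", 0.93, 106, ci_low = 0.88, ci_high = 0.983)
  cs <- monte_carlo_scenario(pop, mort, base, cf, list(a),
                             n_draws = 2000, seed = 17)
  draws_sd <- (cs$percentiles["chd", "p75"] - cs$percentiles["chd", "p25"]) / 1.349
  mc_se <- draws_sd * sqrt(pi / 2) / sqrt(2000)  # SE of a sample median
  expect_lt(abs(cs$percentiles["chd", "p50"] - cs$point[["chd"]]), 2 * mc_se)
})

test_that("widening the RR interval never narrows the credible interval", {
  pop <- tiny_pop(sexes = "male", count = 1e6)
  mort <- tiny_mort(pop, causes = "chd", deaths = 10000)
  base <- tiny_diet(sexes = "male", fruit_mean = 250)
  cf <- as.data.frame(base); cf$fruit_mean <- 356; cf <- diet_distribution(cf)
  widths <- vapply(list(c(0.91, 0.951), c(0.88, 0.983), c(0.83, 1.042)),
                   function(ci) {
    a <- assoc("fruit", "chd", 0.93, 106, ci_low = ci[1], ci_high = ci[2])
    cs <- monte_carlo_scenario(pop, mort, base, cf, list(a),
                               n_draws = 500, seed = 9)
    cs$percentiles["total", "p95"] - cs$percentiles["total", "p5"]
  }, numeric(1))
  expect_false(is.unsorted(widths))
})

test_that("run_all covers every scenario, ranks labels and reproduces", {
  cfg <- small_cfg(seed = 31)
  pop <- generate_population(cfg)
  mort <- generate_mortality(cfg, pop)
  base <- generate_diet(cfg)
  assocs <- read_associations()

  rep1 <- run_all(pop, mort, base, assocs, n_draws = 100, seed = 2)
  expect_length(rep1$summaries, 6)
  expect_setequal(rep1$ranking$label,
                  c("NutriScore", "MTL", "HSR", "RIs", "SENS", "Control"))
  # Control's small purchase differences produce a near-zero point estimate
  ctl <- rep1$summaries[["Control/mean"]]$point[["total"]]
  ns <- rep1$summaries[["NutriScore/mean"]]$point[["total"]]
  expect_lt(abs(ctl), 0.25 * abs(ns))

  rep18 <- run_all(pop, mort, base, assocs,
                   variants = c("mean", "best_case", "worst_case"),
                   n_draws = 20, seed = 2)
  expect_length(rep18$summaries, 18)

  rep2 <- run_all(pop, mort, base, assocs, n_draws = 100, seed = 2)
  expect_identical(write_report(rep1), write_report(rep2))

  expect_error(run_all(pop, mort, base, assocs, labels = "NutriScore",
                       variants = "male_shoppers", n_draws = 10, seed = 1),
               "missing effect table")

  # JSON report is parseable and carries the schema version
  parsed <- jsonlite::fromJSON(write_report(rep1))
  expect_equal(parsed$schema_version, "1.0")
  expect_equal(parsed$seed, 2)
})

test_that("a field-wise dominated label never outranks its dominator", {
  cfg <- small_cfg(seed = 41)
  pop <- generate_population(cfg)
  mort <- generate_mortality(cfg, pop)
  base <- generate_diet(cfg)
  effs <- read_effect_table()
  rep <- run_all(pop, mort, base, beneficial_assocs(), effects = effs,
                 n_draws = 10, seed = 3)
  totals <- vapply(rep$summaries, function(s) s$point[["total"]], numeric(1))
  names(totals) <- sub("/mean", "", names(totals))

  # direction of benefit per effect field
  good_sign <- c(energy = -1, fats = -1, sfa = -1, salt = -1,
                 fibre = 1, fruit = 1, vegetable = 1)
  dominates <- function(a, b) {
    ra <- effs[[paste0(a, "/mean")]]$rel_diff
    rb <- effs[[paste0(b, "/mean")]]$rel_diff
    all(ra * good_sign >= rb * good_sign) && any(ra * good_sign > rb * good_sign)
  }
  labs <- sub("/mean", "", names(totals))
  pairs_checked <- 0
  for (a in labs) for (b in labs) {
    if (a != b && dominates(a, b)) {
      pairs_checked <- pairs_checked + 1
      expect_gte(totals[[a]], totals[[b]])
    }
  }
  expect_gt(pairs_checked, 0)  # the packaged table contains dominance pairs
})
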
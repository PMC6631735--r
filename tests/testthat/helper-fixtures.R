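# In-code fixtures: small stratified tables built at test time.

tiny_strata <- function(sexes = c("male", "female"), age_lows = 60L) {
  g <- expand.grid(sex = sexes, age_low = age_lows, stringsAsFactors = FALSE)
  g$age_high <- g$age_low + 4L
  g[order(g$sex, g$age_low), ]
}

tiny_pop <- function(sexes = c("male", "female"), age_lows = 60L,
                     count = 10000) {
  st <- tiny_strata(sexes, age_lows)
  st$count <- count
  population_table(st)
}

tiny_mort <- function(pop, causes = c("chd", "stroke"), deaths = 500) {
  rows <- do.call(rbind, lapply(causes, function(cid) {
    d <- as.data.frame(pop)[, c("sex", "age_low", "age_high")]
    d$cause_id <- cid
    d$deaths <- deaths
    d
  }))
  mortality_table(rows, pop = pop)
}

# One valid diet row per stratum; any parameter overridable.
tiny_diet <- function(sexes = c("male", "female"), age_lows = 60L, ...) {
  st <- tiny_strata(sexes, age_lows)
  defaults <- list(
    energy_mean = 2000,
    fruit_mean = 150, fruit_sd = 100,
    veg_mean = 200, veg_sd = 80,
    fibre_mean = 19, fibre_sd = 5,
    salt_mean = 7.5, salt_sd = 2,
    fat_pctE_mean = 35, fat_pctE_sd = 8,
    sfa_pctE_mean = 14, sfa_pctE_sd = 4,
    mufa_pctE_mean = 14, mufa_pctE_sd = 4,
    pufa_pctE_mean = 6, pufa_pctE_sd = 2,
    cholesterol_mean = 300, cholesterol_sd = 80)
  over <- list(...)
  defaults[names(over)] <- over
  for (nm in names(defaults)) st[[nm]] <- defaults[[nm]]
  st$fruit_below_one_portion <- portion_fraction(st$fruit_mean, st$fruit_sd, 80)
  st$veg_below_one_portion <- portion_fraction(st$veg_mean, st$veg_sd, 80)
  diet_distribution(st)
}

# Effect table with chosen fields set, remainder zero.
eff <- function(label = "NutriScore", variant = "mean", ...) {
  rel <- setNames(rep(0, 7), c("energy", "fats", "sfa", "salt", "fibre",
                               "fruit", "vegetable"))
  over <- unlist(list(...))
  rel[names(over)] <- over
  effect_table(label, variant, rel)
}

assoc <- function(factor = "fruit", disease = "chd", rr = 0.93, unit = 106,
                  ci_low = rr, ci_high = rr, ...) {
  risk_association(factor, disease, rr, unit, ci_low, ci_high, ...)
}

# Beneficial-only association set: lower energy/fat/SFA/salt and higher
# fibre/fruit/vegetable each reduce deaths through some cause.
beneficial_assocs <- function() {
  list(
    assoc("fruit", "chd", 0.93, 106, 0.90, 0.96),
    assoc("vegetable", "stroke", 0.94, 106, 0.90, 0.98),
    assoc("fibre", "colorectal_cancer", 0.90, 10, 0.86, 0.94),
    assoc("salt", "stroke", 1.04, 1, 1.03, 1.05,
          mediation = "salt_sbp", mediation_coeffs = 1.0),
    assoc("fat_pctE", "chd", 1.02, 1, 1.01, 1.03),
    assoc("sfa_pctE", "chd", 1.04, 1, 1.01, 1.07))
}

small_cfg <- function(seed = 1L, ...) {
  args <- list(seed = seed, total_population = 1e6, total_dietary_deaths = 5000)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}
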
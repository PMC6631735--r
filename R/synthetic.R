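# Synthetic inputs emulating the statistical structure of the national data
# the pipeline was designed for (census age/sex pyramid, cause-of-death
# counts concentrated in older strata, approximately normal stratified
# intakes). They are structural stand-ins: no attempt is made to match true
# census or vital-statistics margins.

#' Configuration for the synthetic-data generators
#'
#' @param seed Integer seed; all three generators derive their own named
#'   stream from it, so a fixed seed yields byte-identical tables and adding
#'   a generator never perturbs another's output.
#' @param n_strata_per_sex Number of 5-year brackets per sex (default 18:
#'   ages 0-4 through 85+).
#' @param total_population Total person count across all strata.
#' @param total_dietary_deaths Total deaths from diet-related NCDs across
#'   all strata and causes.
#' @param diet_profile Named list of national target means for the diet
#'   distribution (energy kcal/d; fruit, veg, fibre, salt g/d; fat, SFA,
#'   MUFA, PUFA %E; cholesterol mg/d).
#' @param age_gradient Positive real; death rates grow as
#'   `exp(age_gradient * bracket_index)`, concentrating deaths in older
#'   strata.
#' @param cv_food,cv_nutrient Coefficients of variation used to set intake
#'   SDs (foods: fruit/vegetable; nutrients: fibre, salt, %E fields,
#'   cholesterol).
#' @param age_amplitude Amplitude of the deterministic linear age trend on
#'   diet means (fraction; oldest vs youngest bracket).
#' @param jitter_sd SD of the multiplicative random jitter on per-stratum
#'   diet means (fraction).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_strata_per_sex = 18L,
                             total_population = 66e6,
                             total_dietary_deaths = 225000,
                             diet_profile = default_diet_profile(),
                             age_gradient = 0.45,
                             cv_food = 0.4,
                             cv_nutrient = 0.25,
                             age_amplitude = 0.05,
                             jitter_sd = 0.02) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (total_population <= 0) stop("total_population must be > 0", call. = FALSE)
  if (total_dietary_deaths < 0) stop("total_dietary_deaths must be >= 0", call. = FALSE)
  if (n_strata_per_sex < 1) stop("n_strata_per_sex must be >= 1", call. = FALSE)
  if (age_gradient <= 0) stop("age_gradient must be > 0", call. = FALSE)
  structure(list(seed = as.integer(seed),
                 n_strata_per_sex = as.integer(n_strata_per_sex),
                 total_population = total_population,
                 total_dietary_deaths = total_dietary_deaths,
                 diet_profile = diet_profile,
                 age_gradient = age_gradient,
                 cv_food = cv_food, cv_nutrient = cv_nutrient,
                 age_amplitude = age_amplitude, jitter_sd = jitter_sd),
            class = "synthetic_config")
}

#' Default national diet-profile targets
#'
#' Adult-survey-scale values: energy at the 1976.3 kcal/d reference used in
#' the worked transposition example, salt in the 6-9 g/d range typical of
#' French adults, and fruit/vegetable/fibre/fat targets at common
#' nutrition-survey magnitudes.
#'
#' @return Named list of target means.
#' @export
default_diet_profile <- function() {
  list(energy = 1976.3,
       fruit = 200, vegetable = 220,
       fibre = 19, salt = 7.5,
       fat_pctE = 38, sfa_pctE = 14.5, mufa_pctE = 14, pufa_pctE = 6,
       cholesterol = 300)
}

# Named RNG streams: each generator seeds its own stream from cfg$seed with
# a fixed offset, run inside a local RNG scope so user RNG state is untouched.
with_stream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max)
  expr
}

synthetic_strata <- function(cfg) {
  age_low <- seq(0L, by = 5L, length.out = cfg$n_strata_per_sex)
  age_high <- age_low + 4L
  age_high[length(age_high)] <- OPEN_AGE_HIGH
  data.frame(sex = rep(c("female", "male"), each = cfg$n_strata_per_sex),
             age_low = rep(age_low, 2), age_high = rep(age_high, 2),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic census-like population table
#'
#' Produces a pyramid-shaped age/sex structure: near-flat counts through
#' mid-life (with small seeded jitter) and exponentially declining counts
#' above age 50 (monotone non-increasing there by construction). The female
#' share is set to 51.6%. Counts are rounded per stratum, so the total
#' matches `cfg$total_population` up to one unit per stratum.
#'
#' @param cfg A [synthetic_config()].
#' @return A [population_table()].
#' @export
generate_population <- function(cfg) {
  st <- synthetic_strata(cfg)
  idx <- (st$age_low %/% 5L)
  w <- with_stream(cfg$seed, 1000L, {
    base <- ifelse(st$age_low < 50,
                   1.0 + stats::runif(nrow(st), -0.06, 0.06),
                   exp(-0.18 * (idx - 9L)))  # bracket 50-54 has idx 10
    base
  })
  sex_w <- ifelse(st$sex == "female", 0.516, 0.484)
  # normalise within sex so the sex split holds regardless of bracket count
  w_norm <- numeric(nrow(st))
  for (s in c("female", "male")) {
    i <- st$sex == s
    w_norm[i] <- w[i] / sum(w[i]) * sex_w[i][1]
  }
  st$count <- round(cfg$total_population * w_norm)
  population_table(st)
}

# Default cause mix: cardiovascular-dominant, reflecting the national
# pattern where CVD and cancer account for the bulk of diet-related deaths.
CAUSE_MIX <- c(chd = 0.25, stroke = 0.15, heart_failure = 0.09,
               hypertensive_disease = 0.06, lung_cancer = 0.14,
               colorectal_cancer = 0.11, other_ncd = 0.20)

#' Generate a synthetic cause-of-death table
#'
#' Deaths rise exponentially with age bracket (`exp(age_gradient * index)`)
#' and follow a cardiovascular-dominant cause mix, with small seeded
#' stratum-level jitter on the mix. Totals are scaled to
#' `cfg$total_dietary_deaths`; per-stratum deaths are capped at the stratum
#' population.
#'
#' @param cfg A [synthetic_config()].
#' @param pop A [population_table()] on the same strata.
#' @return A [mortality_table()].
#' @export
generate_mortality <- function(cfg, pop) {
  st <- synthetic_strata(cfg)
  check_same_strata(st, pop, "synthetic strata", "population")
  key <- stratum_key(pop$sex, pop$age_low)
  counts <- pop$count[match(stratum_key(st$sex, st$age_low), key)]
  idx <- st$age_low %/% 5L
  rate <- exp(cfg$age_gradient * idx)
  # slightly higher male rates, as in national mortality
  rate <- rate * ifelse(st$sex == "male", 1.25, 1.0)
  expected <- counts * rate
  if (sum(expected) == 0) expected[] <- 0 else {
    expected <- expected / sum(expected) * cfg$total_dietary_deaths
  }
  expected <- pmin(expected, counts)
  mix <- with_stream(cfg$seed, 2000L, {
    m <- matrix(rep(CAUSE_MIX, each = nrow(st)), nrow = nrow(st),
                dimnames = list(NULL, names(CAUSE_MIX)))
    jit <- matrix(stats::runif(length(m), 0.9, 1.1), nrow = nrow(st))
    m <- m * jit
    m / rowSums(m)
  })
  rows <- do.call(rbind, lapply(seq_len(nrow(st)), function(i) {
    data.frame(sex = st$sex[i], age_low = st$age_low[i], age_high = st$age_high[i],
               cause_id = names(CAUSE_MIX),
               deaths = expected[i] * mix[i, ],
               stringsAsFactors = FALSE)
  }))
  mortality_table(rows, pop = pop)
}

#' Generate a synthetic baseline diet distribution
#'
#' Per-stratum means are the national targets in `cfg$diet_profile`
#' modulated by (i) a deterministic linear age trend (older strata slightly
#' lower, amplitude `cfg$age_amplitude`) and (ii) a small seeded
#' multiplicative jitter. SDs are set from the per-field coefficient of
#' variation (`cv_food` for fruit/vegetable, `cv_nutrient` otherwise).
#' Below-one-portion fractions are computed from the same normal intake
#' model used by the counterfactual transformation, so baseline tables are
#' internally coherent.
#'
#' @param cfg A [synthetic_config()].
#' @param portion_g Portion size (g) for fruit and vegetable (default 80).
#' @return A [diet_distribution()].
#' @export
generate_diet <- function(cfg, portion_g = 80) {
  st <- synthetic_strata(cfg)
  p <- cfg$diet_profile
  need <- c("energy", "fruit", "vegetable", "fibre", "salt", "fat_pctE",
            "sfa_pctE", "mufa_pctE", "pufa_pctE", "cholesterol")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop(sprintf("diet_profile missing target(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (any(unlist(p[need]) <= 0)) stop("diet_profile targets must be > 0", call. = FALSE)
  if (p$sfa_pctE > p$fat_pctE) stop("diet_profile: sfa_pctE exceeds fat_pctE", call. = FALSE)
  if (p$fat_pctE >= 100) stop("diet_profile: fat_pctE must be < 100", call. = FALSE)
  n <- nrow(st)
  idx <- st$age_low %/% 5L
  trend <- 1 + cfg$age_amplitude * (1 - 2 * idx / max(idx, 1))  # +amp young, -amp old
  jit <- with_stream(cfg$seed, 3000L, {
    matrix(stats::rnorm(n * length(need), 0, cfg$jitter_sd), nrow = n,
           dimnames = list(NULL, need))
  })
  mean_of <- function(field) p[[field]] * trend * exp(jit[, field])
  cv_of <- function(field) {
    if (field %in% c("fruit", "vegetable")) cfg$cv_food else cfg$cv_nutrient
  }
  d <- st
  d$energy_mean <- mean_of("energy")
  d$fruit_mean <- mean_of("fruit")
  d$fruit_sd <- d$fruit_mean * cv_of("fruit")
  d$veg_mean <- mean_of("vegetable")
  d$veg_sd <- d$veg_mean * cv_of("vegetable")
  d$fibre_mean <- mean_of("fibre")
  d$fibre_sd <- d$fibre_mean * cv_of("fibre")
  d$salt_mean <- mean_of("salt")
  d$salt_sd <- d$salt_mean * cv_of("salt")
  # identical age/jitter modulation for fat and SFA keeps sfa <= fat row-wise
  fat_mod <- trend * exp(jit[, "fat_pctE"])
  d$fat_pctE_mean <- p$fat_pctE * fat_mod
  d$fat_pctE_sd <- d$fat_pctE_mean * cv_of("fat_pctE")
  d$sfa_pctE_mean <- p$sfa_pctE * fat_mod
  d$sfa_pctE_sd <- d$sfa_pctE_mean * cv_of("sfa_pctE")
  d$mufa_pctE_mean <- mean_of("mufa_pctE")
  d$mufa_pctE_sd <- d$mufa_pctE_mean * cv_of("mufa_pctE")
  d$pufa_pctE_mean <- mean_of("pufa_pctE")
  d$pufa_pctE_sd <- d$pufa_pctE_mean * cv_of("pufa_pctE")
  d$cholesterol_mean <- mean_of("cholesterol")
  d$cholesterol_sd <- d$cholesterol_mean * cv_of("cholesterol")
  d$fruit_below_one_portion <- portion_fraction(d$fruit_mean, d$fruit_sd, portion_g)
  d$veg_below_one_portion <- portion_fraction(d$veg_mean, d$veg_sd, portion_g)
  diet_distribution(d)
}

#' Write the full set of synthetic fixtures to a directory
#'
#' Writes `population.csv`, `mortality.csv`, `diet.csv` and a copy of the
#' packaged effect-table fixture into `dir`.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_synthetic_fixtures <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pop <- generate_population(cfg)
  mort <- generate_mortality(cfg, pop)
  diet <- generate_diet(cfg)
  paths <- c(file.path(dir, "population.csv"), file.path(dir, "mortality.csv"),
             file.path(dir, "diet.csv"), file.path(dir, "effects.csv"))
  write_population(pop, paths[1])
  write_mortality(mort, paths[2])
  write_diet(diet, paths[3])
  file.copy(fopl_effects_path(), paths[4], overwrite = TRUE)
  invisible(paths)
}
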
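#' @keywords internal
"_PACKAGE"

# Nutrient keys of an effect table: the seven fields measured in the
# purchasing experiment and transposed onto intakes.
EFFECT_KEYS <- c("energy", "fats", "sfa", "salt", "fibre", "fruit", "vegetable")

# Label and variant vocabularies.
LABEL_IDS <- c("NutriScore", "MTL", "HSR", "RIs", "SENS", "Control")
VARIANT_IDS <- c("mean", "best_case", "worst_case", "male_shoppers", "female_shoppers")

# Risk-factor vocabulary: the diet-distribution channels an association may
# act on, and the diet-distribution column holding each factor's mean/SD.
FACTOR_COLUMNS <- list(
  fruit       = c(mean = "fruit_mean",       sd = "fruit_sd"),
  vegetable   = c(mean = "veg_mean",         sd = "veg_sd"),
  fibre       = c(mean = "fibre_mean",       sd = "fibre_sd"),
  salt        = c(mean = "salt_mean",        sd = "salt_sd"),
  fat_pctE    = c(mean = "fat_pctE_mean",    sd = "fat_pctE_sd"),
  sfa_pctE    = c(mean = "sfa_pctE_mean",    sd = "sfa_pctE_sd"),
  mufa_pctE   = c(mean = "mufa_pctE_mean",   sd = "mufa_pctE_sd"),
  pufa_pctE   = c(mean = "pufa_pctE_mean",   sd = "pufa_pctE_sd"),
  cholesterol = c(mean = "cholesterol_mean", sd = "cholesterol_sd"),
  energy      = c(mean = "energy_mean",      sd = NA_character_)
)

DIET_COLUMNS <- c(
  "energy_mean",
  "fruit_mean", "fruit_sd", "fruit_below_one_portion",
  "veg_mean", "veg_sd", "veg_below_one_portion",
  "fibre_mean", "fibre_sd",
  "salt_mean", "salt_sd",
  "fat_pctE_mean", "fat_pctE_sd",
  "sfa_pctE_mean", "sfa_pctE_sd",
  "mufa_pctE_mean", "mufa_pctE_sd",
  "pufa_pctE_mean", "pufa_pctE_sd",
  "cholesterol_mean", "cholesterol_sd"
)

# Sentinel upper bound encoding the open-ended "85+" census bracket.
OPEN_AGE_HIGH <- 120L

#' Default cause-of-death registry
#'
#' The minimal set of diet-related non-communicable disease causes the
#' engine is tested against: coronary heart disease, stroke, heart failure,
#' hypertensive disease, lung and colorectal cancer, plus a catch-all
#' `other_ncd` bucket. Each cause belongs to one of the groups
#' `cardiovascular`, `cancer` or `other`, the grouping used when results
#' are aggregated. The registry is an ordinary data frame and can be
#' extended with further pre-grouped cause ids.
#'
#' @return A data frame with columns `cause_id`, `name`, `group`.
#' @export
#' @examples
#' default_cause_registry()
default_cause_registry <- function() {
  data.frame(
    cause_id = c("chd", "stroke", "heart_failure", "hypertensive_disease",
                 "lung_cancer", "colorectal_cancer", "other_ncd"),
    name = c("Coronary heart disease", "Stroke", "Heart failure",
             "Hypertensive disease", "Lung cancer", "Colorectal cancer",
             "Other diet-related NCD"),
    group = c("cardiovascular", "cardiovascular", "cardiovascular",
              "cardiovascular", "cancer", "cancer", "other"),
    stringsAsFactors = FALSE
  )
}

# ---- stratum helpers -------------------------------------------------------

stratum_key <- function(sex, age_low) paste(sex, age_low, sep = ":")

# Validate a (sex, age_low, age_high) frame: 5-year closed brackets,
# disjoint and contiguous within each sex, identical bracket sets per sex.
validate_strata <- function(df, what = "table") {
  req <- c("sex", "age_low", "age_high")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s): %s", what, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (!all(df$sex %in% c("male", "female"))) {
    bad <- which(!df$sex %in% c("male", "female"))[1]
    stop(sprintf("%s: row %d has invalid sex '%s'", what, bad, df$sex[bad]),
         call. = FALSE)
  }
  if (any(df$age_low < 0)) {
    stop(sprintf("%s: negative age_low (row %d)", what, which(df$age_low < 0)[1]),
         call. = FALSE)
  }
  if (any(df$age_low %% 5 != 0)) {
    stop(sprintf("%s: age_low must be a multiple of 5 (row %d)",
                 what, which(df$age_low %% 5 != 0)[1]), call. = FALSE)
  }
  ok_high <- df$age_high == df$age_low + 4L | df$age_high == OPEN_AGE_HIGH
  if (!all(ok_high)) {
    stop(sprintf("%s: age_high must be age_low + 4 (or %d for the open top bracket); row %d",
                 what, OPEN_AGE_HIGH, which(!ok_high)[1]), call. = FALSE)
  }
  for (s in unique(df$sex)) {
    lows <- sort(unique(df$age_low[df$sex == s]))
    if (anyDuplicated(df$age_low[df$sex == s]) &&
        !all(table(df$age_low[df$sex == s]) ==
             table(df$age_low[df$sex == s])[1])) {
      stop(sprintf("%s: duplicated brackets for sex %s", what, s), call. = FALSE)
    }
    if (length(lows) > 1 && !all(diff(lows) == 5)) {
      stop(sprintf("%s: brackets for sex %s are not contiguous 5-year brackets",
                   what, s), call. = FALSE)
    }
  }
  invisible(df)
}

# Assert that two stratified tables are indexed by the identical stratum set.
check_same_strata <- function(a, b, what_a, what_b) {
  ka <- sort(unique(stratum_key(a$sex, a$age_low)))
  kb <- sort(unique(stratum_key(b$sex, b$age_low)))
  if (!identical(ka, kb)) {
    stop(sprintf("stratum mismatch between %s and %s", what_a, what_b),
         call. = FALSE)
  }
  invisible(TRUE)
}

sort_strata <- function(df) {
  df[order(df$sex, df$age_low), , drop = FALSE]
}

# ---- population ------------------------------------------------------------

#' Construct and validate a population table
#'
#' @param df Data frame with columns `sex`, `age_low`, `age_high`, `count`
#'   (one row per sex x 5-year age bracket; the open-ended top bracket is
#'   encoded with `age_high = 120`).
#' @return A `population_table` (data frame sorted by sex, age_low).
#' @export
population_table <- function(df) {
  validate_strata(df, "population table")
  if (!"count" %in% names(df)) stop("population table: missing column: count", call. = FALSE)
  if (any(df$count < 0)) {
    stop(sprintf("population table: negative count (row %d)",
                 which(df$count < 0)[1]), call. = FALSE)
  }
  if (anyDuplicated(stratum_key(df$sex, df$age_low))) {
    stop("population table: duplicated stratum rows", call. = FALSE)
  }
  if (sum(df$count) <= 0) stop("population table: total population must be > 0", call. = FALSE)
  df <- sort_strata(df[, c("sex", "age_low", "age_high", "count")])
  rownames(df) <- NULL
  structure(df, class = c("population_table", "data.frame"))
}

#' Read a population table from CSV
#'
#' @param path CSV file with header `sex,age_low,age_high,count`.
#' @return A validated [population_table()].
#' @export
read_population <- function(path) {
  population_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a population table to CSV
#' @param pop A `population_table`.
#' @param path Output path.
#' @export
write_population <- function(pop, path) {
  utils::write.csv(as.data.frame(pop), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- mortality -------------------------------------------------------------

#' Construct and validate a mortality table
#'
#' Death counts are stored as reals (model outputs are expectations, and
#' scaled or sex-weighted tables must remain valid).
#'
#' @param df Data frame with columns `sex`, `age_low`, `age_high`,
#'   `cause_id`, `deaths`.
#' @param registry Cause registry data frame (see
#'   [default_cause_registry()]); rows with a `cause_id` absent from it are
#'   rejected.
#' @param pop Optional `population_table`; when supplied, strata whose total
#'   deaths exceed the stratum population trigger a warning.
#' @return A `mortality_table` (data frame with the registry attached as an
#'   attribute).
#' @export
mortality_table <- function(df, registry = default_cause_registry(), pop = NULL) {
  validate_strata(df, "mortality table")
  req <- c("cause_id", "deaths")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop(sprintf("mortality table: missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  unknown <- setdiff(unique(df$cause_id), registry$cause_id)
  if (length(unknown)) {
    stop(sprintf("mortality table: unknown cause_id: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (any(df$deaths < 0)) {
    stop(sprintf("mortality table: negative deaths (row %d)",
                 which(df$deaths < 0)[1]), call. = FALSE)
  }
  if (anyDuplicated(paste(df$sex, df$age_low, df$cause_id))) {
    stop("mortality table: duplicated (stratum, cause) rows", call. = FALSE)
  }
  df <- df[order(df$sex, df$age_low, df$cause_id),
           c("sex", "age_low", "age_high", "cause_id", "deaths")]
  rownames(df) <- NULL
  if (!is.null(pop)) {
    tot <- stats::aggregate(deaths ~ sex + age_low, df, sum)
    key <- stratum_key(pop$sex, pop$age_low)
    pc <- pop$count[match(stratum_key(tot$sex, tot$age_low), key)]
    over <- which(tot$deaths > pc)
    if (length(over)) {
      warning(sprintf("mortality table: deaths exceed population in stratum %s %d-%d",
                      tot$sex[over[1]], tot$age_low[over[1]],
                      tot$age_low[over[1]] + 4L), call. = FALSE)
    }
  }
  structure(df, registry = registry, class = c("mortality_table", "data.frame"))
}

#' Read a mortality table from CSV
#'
#' @param path CSV file with header `sex,age_low,age_high,cause_id,deaths`.
#' @param registry Cause registry; unknown cause ids are an error.
#' @param pop Optional population table for a deaths-vs-population cross-check.
#' @return A validated [mortality_table()].
#' @export
read_mortality <- function(path, registry = default_cause_registry(), pop = NULL) {
  mortality_table(utils::read.csv(path, stringsAsFactors = FALSE), registry, pop)
}

#' Write a mortality table to CSV
#' @param mort A `mortality_table`.
#' @param path Output path.
#' @export
write_mortality <- function(mort, path) {
  utils::write.csv(as.data.frame(mort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up the cause group of a cause id
#' @param cause_id Cause identifier(s).
#' @param registry Cause registry data frame.
#' @return Character vector of groups (`cardiovascular`, `cancer`, `other`).
#' @export
cause_group <- function(cause_id, registry = default_cause_registry()) {
  registry$group[match(cause_id, registry$cause_id)]
}

# ---- diet distribution -----------------------------------------------------

#' Construct and validate a diet distribution
#'
#' A stratified table of intake-distribution parameters: mean energy
#' (kcal/d); mean and SD of fruit, vegetable (g/d) with the fraction of the
#' stratum consuming less than one daily portion; mean and SD of fibre and
#' salt (g/d); mean and SD of total fat, SFA, MUFA and PUFA (% of total
#' energy); mean and SD of dietary cholesterol (mg/d).
#'
#' @param df Data frame with columns `sex`, `age_low`, `age_high` and the 21
#'   parameter columns (see [diet_parameter_columns()]).
#' @return A `diet_distribution` (data frame sorted by sex, age_low).
#' @export
diet_distribution <- function(df) {
  validate_strata(df, "diet distribution")
  miss <- setdiff(DIET_COLUMNS, names(df))
  if (length(miss)) {
    stop(sprintf("diet distribution: missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  means <- grep("_mean$", DIET_COLUMNS, value = TRUE)
  sds <- grep("_sd$", DIET_COLUMNS, value = TRUE)
  for (m in means) {
    if (any(df[[m]] <= 0)) {
      stop(sprintf("diet distribution: %s must be > 0 (row %d)",
                   m, which(df[[m]] <= 0)[1]), call. = FALSE)
    }
  }
  for (s in sds) {
    if (any(df[[s]] < 0)) {
      stop(sprintf("diet distribution: %s must be >= 0 (row %d)",
                   s, which(df[[s]] < 0)[1]), call. = FALSE)
    }
  }
  for (f in c("fruit_below_one_portion", "veg_below_one_portion")) {
    if (any(df[[f]] < 0 | df[[f]] > 1)) {
      stop(sprintf("diet distribution: %s must lie in [0, 1] (row %d)",
                   f, which(df[[f]] < 0 | df[[f]] > 1)[1]), call. = FALSE)
    }
  }
  if (any(df$sfa_pctE_mean > df$fat_pctE_mean)) {
    stop(sprintf("diet distribution: sfa_pctE_mean exceeds fat_pctE_mean (row %d)",
                 which(df$sfa_pctE_mean > df$fat_pctE_mean)[1]), call. = FALSE)
  }
  if (any(df$fat_pctE_mean >= 100)) {
    stop("diet distribution: fat_pctE_mean must be < 100", call. = FALSE)
  }
  df <- sort_strata(df[, c("sex", "age_low", "age_high", DIET_COLUMNS)])
  rownames(df) <- NULL
  structure(df, class = c("diet_distribution", "data.frame"))
}

#' Names of the diet-distribution parameter columns
#' @return Character vector of the 21 parameter column names.
#' @export
diet_parameter_columns <- function() DIET_COLUMNS

#' Read a diet distribution from CSV
#' @param path CSV with `sex`, `age_low`, `age_high` and the parameter columns.
#' @return A validated [diet_distribution()].
#' @export
read_diet <- function(path) {
  diet_distribution(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a diet distribution to CSV
#' @param diet A `diet_distribution`.
#' @param path Output path.
#' @export
write_diet <- function(diet, path) {
  utils::write.csv(as.data.frame(diet), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- effect tables ---------------------------------------------------------

#' Construct and validate an effect table
#'
#' One label x variant set of relative differences (%) in the nutrient
#' content of purchases between the labelled and the reference situation,
#' covering the seven transposed fields: energy, fats, SFA, salt, fibre,
#' fruit, vegetable.
#'
#' @param label Label id (one of `r paste(LABEL_IDS, collapse = ", ")`).
#' @param variant Variant id (`mean`, `best_case`, `worst_case`,
#'   `male_shoppers`, `female_shoppers`).
#' @param rel_diff Named numeric of signed percent changes, names exactly
#'   the seven nutrient keys.
#' @return An `effect_table` object.
#' @export
#' @examples
#' effect_table("NutriScore", "mean",
#'   c(energy = -9.04, fats = -21.38, sfa = -29.89, salt = -4.1,
#'     fibre = 7.21, fruit = 12.36, vegetable = 5.38))
effect_table <- function(label, variant, rel_diff) {
  label <- match.arg(label, LABEL_IDS)
  variant <- match.arg(variant, VARIANT_IDS)
  miss <- setdiff(EFFECT_KEYS, names(rel_diff))
  if (length(miss)) {
    stop(sprintf("effect table %s/%s: missing nutrient key(s): %s",
                 label, variant, paste(miss, collapse = ", ")), call. = FALSE)
  }
  rel_diff <- rel_diff[EFFECT_KEYS]
  if (any(!is.finite(rel_diff))) {
    stop(sprintf("effect table %s/%s: non-finite relative difference", label, variant),
         call. = FALSE)
  }
  if (any(rel_diff <= -100)) {
    stop(sprintf("effect table %s/%s: relative difference <= -100%% for %s",
                 label, variant, names(rel_diff)[rel_diff <= -100][1]), call. = FALSE)
  }
  structure(list(label = label, variant = variant, rel_diff = rel_diff),
            class = "effect_table")
}

#' @export
print.effect_table <- function(x, ...) {
  cat(sprintf("Effect table: %s (%s variant)\n", x$label, x$variant))
  print(round(x$rel_diff, 2))
  invisible(x)
}

#' Read effect tables from CSV
#'
#' The long-format CSV has columns `label`, `variant`, `nutrient`, `value`
#' (percent). One [effect_table()] is built per (label, variant) pair; a
#' pair missing any of the seven nutrient keys is an error.
#'
#' @param path CSV path. Defaults to the packaged fixture reproducing the
#'   purchasing-experiment effect table (6 labels x 3 variants).
#' @return Named list of `effect_table` objects, names `"label/variant"`.
#' @export
read_effect_table <- function(path = fopl_effects_path()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("label", "variant", "nutrient", "value")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop(sprintf("effect table file: missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  out <- list()
  for (lab in unique(df$label)) {
    for (v in unique(df$variant[df$label == lab])) {
      sub <- df[df$label == lab & df$variant == v, ]
      rel <- stats::setNames(sub$value, sub$nutrient)
      out[[paste(lab, v, sep = "/")]] <- effect_table(lab, v, rel)
    }
  }
  out
}

#' Path of the packaged purchasing-experiment effect-table fixture
#' @return File path of the CSV shipped in `inst/extdata`.
#' @export
fopl_effects_path <- function() {
  system.file("extdata", "effects_table1.csv", package = "foplmort", mustWork = TRUE)
}

#' Write a list of effect tables to CSV
#' @param effects Named list of `effect_table` objects.
#' @param path Output path.
#' @export
write_effect_tables <- function(effects, path) {
  rows <- do.call(rbind, lapply(effects, function(e) {
    data.frame(label = e$label, variant = e$variant,
               nutrient = names(e$rel_diff), value = unname(e$rel_diff),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- risk associations -----------------------------------------------------

#' Construct and validate a risk association
#'
#' One risk-factor to disease link: a relative risk applied log-linearly per
#' `unit` of the factor (e.g. CHD relative risk per 106 g/d of fruit), with
#' its 95% CI, and an optional linear mediation chain (e.g. salt acting on
#' stroke through systolic blood pressure, in which case `rr` is per unit of
#' the final mediator and `mediation_coeffs` carries the linear
#' exposure-to-mediator slopes, applied in order).
#'
#' @param factor Risk factor (one of the diet-distribution channels:
#'   fruit, vegetable, fibre, salt, fat_pctE, sfa_pctE, mufa_pctE,
#'   pufa_pctE, cholesterol, energy).
#' @param disease Cause id in the registry.
#' @param rr Relative risk per `unit` (> 0).
#' @param unit Amount of the factor (or final mediator) per one RR
#'   application (> 0).
#' @param ci_low,ci_high 95% CI bounds of `rr`; must bracket it.
#' @param form Dose-response form; only `log_linear` is defined.
#' @param mediation Chain id: `none` (direct), `salt_sbp` or `energy_bmi`.
#' @param mediation_coeffs Numeric vector of linear slopes (units-out per
#'   unit-in) composing exposure into the final mediator; required unless
#'   `mediation = "none"`.
#' @return A `risk_association` object.
#' @export
risk_association <- function(factor, disease, rr, unit, ci_low, ci_high,
                             form = "log_linear", mediation = "none",
                             mediation_coeffs = numeric(0)) {
  factor <- match.arg(factor, names(FACTOR_COLUMNS))
  form <- match.arg(form, "log_linear")
  mediation <- match.arg(mediation, c("none", "salt_sbp", "energy_bmi"))
  if (!is.numeric(rr) || rr <= 0) {
    stop(sprintf("association %s -> %s: rr must be > 0", factor, disease), call. = FALSE)
  }
  if (!is.numeric(unit) || unit <= 0) {
    stop(sprintf("association %s -> %s: unit must be > 0", factor, disease), call. = FALSE)
  }
  if (!is.finite(ci_low) || !is.finite(ci_high) || ci_low > rr || ci_high < rr) {
    stop(sprintf("association %s -> %s: CI must satisfy ci_low <= rr <= ci_high",
                 factor, disease), call. = FALSE)
  }
  if (mediation != "none" && length(mediation_coeffs) == 0) {
    stop(sprintf("association %s -> %s: mediation chain '%s' requires mediation_coeffs",
                 factor, disease, mediation), call. = FALSE)
  }
  if (length(mediation_coeffs) && any(!is.finite(mediation_coeffs))) {
    stop(sprintf("association %s -> %s: non-finite mediation coefficient",
                 factor, disease), call. = FALSE)
  }
  structure(list(factor = factor, disease = disease, rr = rr, unit = unit,
                 ci_low = ci_low, ci_high = ci_high, form = form,
                 mediation = mediation,
                 mediation_coeffs = as.numeric(mediation_coeffs)),
            class = "risk_association")
}

#' @export
print.risk_association <- function(x, ...) {
  med <- if (x$mediation == "none") "" else sprintf(" via %s", x$mediation)
  cat(sprintf("%s -> %s%s: RR %.3f (%.3f-%.3f) per %g\n",
              x$factor, x$disease, med, x$rr, x$ci_low, x$ci_high, x$unit))
  invisible(x)
}

#' Read risk associations from a YAML config
#'
#' The config holds a top-level `associations:` list; each entry has keys
#' `factor`, `disease`, `rr`, `unit`, `ci_low`, `ci_high` and optionally
#' `form`, `mediation`, `mediation_coeffs`. The packaged
#' `associations_fixture.yaml` ships illustrative default values (the
#' underlying meta-analysis estimates are not distributed with this
#' package); replace it with your own calibrated table for substantive use.
#'
#' @param path YAML file path. Defaults to the packaged illustrative fixture.
#' @param registry Cause registry used to validate disease ids.
#' @return List of `risk_association` objects (empty, with a warning, if the
#'   config lists none).
#' @export
read_associations <- function(path = fopl_associations_path(),
                              registry = default_cause_registry()) {
  doc <- yaml::read_yaml(path)
  entries <- doc$associations
  if (is.null(entries) || length(entries) == 0) {
    warning("association config is empty; no risk pathways loaded", call. = FALSE)
    return(list())
  }
  out <- lapply(entries, function(e) {
    a <- risk_association(
      factor = e$factor, disease = e$disease, rr = e$rr, unit = e$unit,
      ci_low = e$ci_low, ci_high = e$ci_high,
      form = if (is.null(e$form)) "log_linear" else e$form,
      mediation = if (is.null(e$mediation)) "none" else e$mediation,
      mediation_coeffs = if (is.null(e$mediation_coeffs)) numeric(0)
                         else unlist(e$mediation_coeffs)
    )
    if (!a$disease %in% registry$cause_id) {
      stop(sprintf("association %s -> %s: disease not in cause registry",
                   a$factor, a$disease), call. = FALSE)
    }
    a
  })
  out
}

#' Path of the packaged illustrative association fixture
#' @return File path of the YAML shipped in `inst/extdata`.
#' @export
fopl_associations_path <- function() {
  system.file("extdata", "associations_fixture.yaml", package = "foplmort",
              mustWork = TRUE)
}
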
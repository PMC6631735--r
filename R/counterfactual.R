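# Counterfactual ("labelled") diet construction: the label-induced relative
# purchase differences are transposed multiplicatively onto the baseline
# stratified intake parameters. Energy, fruit, vegetable, fibre and salt are
# scaled directly; fat and SFA effects are interpreted in gram space
# (purchase differences are measured on cart nutrient content in grams) and
# re-expressed as % of the counterfactual energy; MUFA, PUFA and cholesterol
# are untouched in gram space, their %E shifting passively with energy.

KCAL_PER_G_FAT <- 9

#' Scenario specification for the counterfactual transformation
#'
#' @param label Label id selecting the effect table.
#' @param variant Variant id (`mean`, `best_case`, `worst_case`, ...).
#' @param portion_size_fruit,portion_size_veg Portion sizes in grams used
#'   when recomputing below-one-portion fractions (default 80 g, the
#'   standard fruit/vegetable portion).
#' @param sd_scaling `"proportional"` (SDs keep a constant coefficient of
#'   variation; default) or `"fixed"` (SDs carried unchanged, a pure
#'   location shift, offered for sensitivity analysis).
#' @param fat_effect_space `"grams"` (default; fat and SFA purchase
#'   differences applied to gram intakes, then re-expressed as %E of the
#'   counterfactual energy) or `"pctE"` (differences applied directly to the
#'   %E values, for sensitivity).
#' @param portion_handling `"recompute"` (default; below-one-portion
#'   fractions recomputed from the counterfactual normal intake model) or
#'   `"carry"` (baseline fractions carried over unchanged).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(label = "NutriScore", variant = "mean",
                          portion_size_fruit = 80, portion_size_veg = 80,
                          sd_scaling = c("proportional", "fixed"),
                          fat_effect_space = c("grams", "pctE"),
                          portion_handling = c("recompute", "carry")) {
  if (portion_size_fruit <= 0 || portion_size_veg <= 0) {
    stop("portion sizes must be > 0", call. = FALSE)
  }
  structure(list(label = match.arg(label, LABEL_IDS),
                 variant = match.arg(variant, VARIANT_IDS),
                 portion_size_fruit = portion_size_fruit,
                 portion_size_veg = portion_size_veg,
                 sd_scaling = match.arg(sd_scaling),
                 fat_effect_space = match.arg(fat_effect_space),
                 portion_handling = match.arg(portion_handling)),
            class = "scenario_spec")
}

#' Apply a relative difference to an intake mean
#'
#' The elementary transposition step: a signed percent change observed on
#' purchases is applied multiplicatively to an intake quantity, e.g. a
#' -9.04% energy difference turns a 1976.3 kcal/d reference intake into
#' 1797.66 kcal/d.
#'
#' @param mean Non-negative quantity (any intake unit).
#' @param rel_diff_pct Signed percent change; must exceed -100 (an intake
#'   cannot become negative).
#' @return `mean * (1 + rel_diff_pct / 100)`, vectorised.
#' @export
#' @examples
#' apply_relative_difference(1976.3, -9.04)  # 1797.66
apply_relative_difference <- function(mean, rel_diff_pct) {
  if (any(mean < 0)) stop("mean must be >= 0", call. = FALSE)
  if (any(rel_diff_pct <= -100)) {
    stop("relative difference <= -100% would imply negative intake", call. = FALSE)
  }
  mean * (1 + rel_diff_pct / 100)
}

#' Fraction of a stratum below one daily portion
#'
#' Under the normal intake model N(mean, sd^2), the fraction consuming
#' strictly less than one portion is `pnorm((portion - mean) / sd)`. With
#' sd = 0 the distribution is degenerate at the mean and the fraction is the
#' indicator of `mean < portion` (intake exactly equal to the portion counts
#' as meeting it).
#'
#' @param mean,sd Intake mean and SD (g/d), `sd >= 0`.
#' @param portion Portion size (g).
#' @return Fraction in \[0, 1\], vectorised over `mean`/`sd`.
#' @export
#' @examples
#' portion_fraction(150, 100, 80)  # ~0.242
portion_fraction <- function(mean, sd, portion) {
  if (any(sd < 0)) stop("sd must be >= 0", call. = FALSE)
  out <- ifelse(sd == 0, as.numeric(mean < portion),
                stats::pnorm((portion - mean) / ifelse(sd == 0, 1, sd)))
  out
}

scale_sd <- function(sd_base, mean_base, mean_cf, sd_scaling) {
  if (sd_scaling == "fixed") return(sd_base)
  ratio <- ifelse(mean_base > 0, mean_cf / mean_base, 1)
  sd_base * ratio
}

#' Build the counterfactual ("labelled") diet distribution
#'
#' Applies one effect table to a baseline diet distribution, stratum by
#' stratum. Energy, fruit, vegetable, fibre and salt means are scaled by
#' their relative differences. Fat and SFA are handled in gram space by
#' default: the baseline %E is converted to g/d via the baseline energy
#' (9 kcal/g), scaled by the purchase difference, and re-expressed as %E of
#' the counterfactual energy. MUFA, PUFA and cholesterol intakes are held
#' fixed in gram/mg space (no purchase effect was measured for them); the
#' %E fields are recomputed against the counterfactual energy. SDs follow
#' `spec$sd_scaling` and below-one-portion fractions follow
#' `spec$portion_handling`.
#'
#' @param base A [diet_distribution()].
#' @param effects An [effect_table()] whose label/variant match `spec`.
#' @param spec A [scenario_spec()].
#' @return A validated counterfactual [diet_distribution()].
#' @export
build_counterfactual <- function(base, effects, spec = scenario_spec()) {
  stopifnot(inherits(base, "diet_distribution"), inherits(effects, "effect_table"),
            inherits(spec, "scenario_spec"))
  e <- effects$rel_diff
  cf <- as.data.frame(base)

  energy_factor <- 1 + e[["energy"]] / 100
  cf$energy_mean <- apply_relative_difference(base$energy_mean, e[["energy"]])

  direct <- list(fruit = c("fruit_mean", "fruit_sd"),
                 vegetable = c("veg_mean", "veg_sd"),
                 fibre = c("fibre_mean", "fibre_sd"),
                 salt = c("salt_mean", "salt_sd"))
  for (k in names(direct)) {
    mcol <- direct[[k]][1]; scol <- direct[[k]][2]
    cf[[mcol]] <- apply_relative_difference(base[[mcol]], e[[k]])
    cf[[scol]] <- scale_sd(base[[scol]], base[[mcol]], cf[[mcol]], spec$sd_scaling)
  }

  if (spec$fat_effect_space == "grams") {
    # %E -> g/d at baseline energy, scale grams, re-express as %E of
    # counterfactual energy; algebraically pctE * (1+e_fat)/(1+e_energy)
    fat_g <- base$fat_pctE_mean / 100 * base$energy_mean / KCAL_PER_G_FAT
    fat_g_cf <- apply_relative_difference(fat_g, e[["fats"]])
    cf$fat_pctE_mean <- fat_g_cf * KCAL_PER_G_FAT / cf$energy_mean * 100
    sfa_g <- base$sfa_pctE_mean / 100 * base$energy_mean / KCAL_PER_G_FAT
    sfa_g_cf <- apply_relative_difference(sfa_g, e[["sfa"]])
    cf$sfa_pctE_mean <- sfa_g_cf * KCAL_PER_G_FAT / cf$energy_mean * 100
  } else {
    cf$fat_pctE_mean <- apply_relative_difference(base$fat_pctE_mean, e[["fats"]])
    cf$sfa_pctE_mean <- apply_relative_difference(base$sfa_pctE_mean, e[["sfa"]])
  }
  cf$fat_pctE_sd <- scale_sd(base$fat_pctE_sd, base$fat_pctE_mean,
                             cf$fat_pctE_mean, spec$sd_scaling)
  cf$sfa_pctE_sd <- scale_sd(base$sfa_pctE_sd, base$sfa_pctE_mean,
                             cf$sfa_pctE_mean, spec$sd_scaling)
  if (any(cf$sfa_pctE_mean > cf$fat_pctE_mean + 1e-9)) {
    stop(sprintf("inconsistent effect table %s/%s: counterfactual SFA %%E exceeds total fat %%E",
                 effects$label, effects$variant), call. = FALSE)
  }
  if (any(cf$fat_pctE_mean >= 100)) {
    stop(sprintf("inconsistent effect table %s/%s: counterfactual fat %%E >= 100",
                 effects$label, effects$variant), call. = FALSE)
  }

  # MUFA/PUFA grams fixed; %E shifts passively with energy
  for (cols in list(c("mufa_pctE_mean", "mufa_pctE_sd"),
                    c("pufa_pctE_mean", "pufa_pctE_sd"))) {
    cf[[cols[1]]] <- base[[cols[1]]] / energy_factor
    cf[[cols[2]]] <- scale_sd(base[[cols[2]]], base[[cols[1]]],
                              cf[[cols[1]]], spec$sd_scaling)
  }
  # cholesterol is mg/d, not %E: untouched
  cf$cholesterol_mean <- base$cholesterol_mean
  cf$cholesterol_sd <- base$cholesterol_sd

  if (spec$portion_handling == "recompute") {
    cf$fruit_below_one_portion <- portion_fraction(cf$fruit_mean, cf$fruit_sd,
                                                   spec$portion_size_fruit)
    cf$veg_below_one_portion <- portion_fraction(cf$veg_mean, cf$veg_sd,
                                                 spec$portion_size_veg)
  } else {
    cf$fruit_below_one_portion <- base$fruit_below_one_portion
    cf$veg_below_one_portion <- base$veg_below_one_portion
  }
  diet_distribution(cf)
}

#' A null (all-zero) effect table
#'
#' Convenience constructor for the identity scenario: applying it leaves
#' the baseline distribution unchanged.
#'
#' @param label,variant Identifiers for the resulting table.
#' @return An [effect_table()] with all seven relative differences 0.
#' @export
null_effect_table <- function(label = "Control", variant = "mean") {
  effect_table(label, variant, stats::setNames(rep(0, length(EFFECT_KEYS)), EFFECT_KEYS))
}
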
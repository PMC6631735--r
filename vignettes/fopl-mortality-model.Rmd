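---
title: "Estimating deaths averted by front-of-pack nutrition labels: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating deaths averted by front-of-pack nutrition labels: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foplmort)
```

## The question the model answers

Front-of-pack nutrition labels (FoPLs) such as the Nutri-Score, Multiple
Traffic Lights (MTL), Health Star Rating (HSR), Reference Intakes (RIs) and
SENS change what households buy. Experimental shopping studies summarise
that change as a *relative difference* (in %) in the nutrient content of the
shopping cart between an unlabelled reference situation and a labelled one:
for example, a label may be associated with 9% less energy and 12% more
fruit in the cart. `foplmort` converts such purchase-level effects into an
estimate of the number of deaths from diet-related non-communicable
diseases (NCDs) that would be averted or delayed if the label were in
universal use, with credible intervals, and ranks label formats by that
impact.

The approach is a comparative risk assessment (CRA) in the style of the
PRIME family of macro-simulation models. It is *static*: no time dynamics,
no morbidity, no lag between exposure change and outcome, no interactions
between risk factors. It compares expected deaths under two intake
distributions — observed (baseline) and hypothetical (labelled,
counterfactual) — in a population stratified by sex and 5-year age bracket.

## Data model

All inputs are indexed by *stratum* (sex × 5-year age bracket; the open
top bracket "85+" is encoded with `age_high = 120`):

* a **population table** (person counts),
* a **mortality table** (deaths per stratum and pre-grouped cause id, as
  reals, since model outputs are expectations),
* a **diet distribution**: per-stratum mean energy (kcal/d); mean and SD of
  fruit, vegetable (g/d) with the fraction of the stratum below one daily
  portion; mean and SD of fibre and salt (g/d), of total fat, SFA, MUFA and
  PUFA (% of total energy, %E), and of cholesterol (mg/d),
* **effect tables**: one per label × variant, holding the seven transposed
  relative differences (energy, fats, SFA, salt, fibre, fruit, vegetable).
  The packaged fixture carries the published mean, best-case (first
  quartile of purchase-quality change) and worst-case (fourth quartile)
  variants for all six experimental arms, including the no-label control,
* **risk associations**: log-linear relative risks per unit of intake with
  95% CIs, optionally acting through a linear mediation chain.

The shipped association table (`associations_fixture.yaml`) is an
*illustrative fixture*: the meta-analytic estimates used for substantive
national results are not redistributed here, so the file contains
plausible, clearly-labelled default values in the range of the published
literature. All results computed with it characterise the pipeline, not
any real population.

## Counterfactual construction

For each stratum, the labelled diet is obtained multiplicatively:

* energy, fruit, vegetable, fibre and salt means are scaled by
  $1 + \delta/100$ where $\delta$ is the field's relative difference;
* **fat and SFA act in gram space**: purchase differences are measured on
  cart nutrient *content* (grams), while the model consumes %E. The
  baseline %E is converted to g/d via the baseline energy (9 kcal/g of
  fat), scaled by $\delta$, and re-expressed as %E of the *counterfactual*
  energy. Algebraically the %E moves by
  $(1+\delta_\text{fat}/100)/(1+\delta_\text{energy}/100)$. A sensitivity
  flag (`fat_effect_space = "pctE"`) applies the difference to %E directly;
* MUFA, PUFA and cholesterol were not measured in the purchasing
  experiment; their gram (mg) intakes are held fixed, so their %E fields
  shift passively with energy;
* **SDs scale proportionally with means by default** (constant coefficient
  of variation). Only relative differences are transposed, and nothing is
  known about dispersion change; a pure location shift would leave
  implausibly heavy lower tails, so the multiplicative reading is the
  default and `sd_scaling = "fixed"` is offered for sensitivity;
* **below-one-portion fractions are recomputed** under a normal intake
  model, $\Phi((p - \mu)/\sigma)$ with the standard $p = 80$ g portion;
  with $\sigma = 0$ the fraction is the indicator $\mu < p$ (intake exactly
  equal to one portion counts as meeting it — a literal reading of "less
  than one portion"). Whether the original analysis recomputed these
  fractions or carried the baseline values is not recoverable; both
  behaviours are available (`portion_handling = "recompute"` / `"carry"`)
  and the default is recomputation, which keeps the counterfactual table
  internally coherent with its own means and SDs;
* sugars, although measured in purchasing experiments, are not among the
  transposed fields and are excluded.

A relative difference of $-100\%$ or below is rejected (negative intake),
and an effect table whose transposed SFA exceeds total fat is flagged as
inconsistent.

## The comparative risk assessment engine

Relative risks are log-linear per unit: $RR(x) = r^{x/u}$ for an
association with point estimate $r$ per $u$ units (e.g. $r = 0.93$ per
$u = 106$ g/d of fruit). For a shift of the stratum mean from $\mu_0$ to
$\mu_1$ the default risk ratio is the **mean-shift** form

$$\rho = r^{(\mu_1 - \mu_0)/u},$$

matching the convention of transposing means. A
**distribution-integrated** alternative computes
$\rho = \mathbb{E}[RR(X_1)]/\mathbb{E}[RR(X_0)]$ with $X_i$ normal, by
adaptive quadrature of $e^{bx}$ against the normal density over ±10 SD
(relative tolerance $10^{-10}$); with degenerate SDs it collapses onto the
mean-shift form. Mediated pathways (salt → systolic blood pressure →
stroke/CHD/hypertensive disease/heart failure) propagate the exposure
delta through linear slopes (mmHg per g/d of salt) and exponentiate the
final RR per mmHg.

Counterfactual deaths in a (stratum, cause) cell are the baseline deaths
times the product of the risk ratios of all associations targeting that
cause; causes without associations pass through unchanged. Deaths averted
or delayed are the difference, summed into cardiovascular, cancer, other
and total groups. Design choices made where the source material is silent:

* RRs are age-invariant (no age-specific attenuation is supplied by
  default);
* the below-one-portion fractions are carried as descriptive parameters
  and *not* used as a second risk channel, to avoid double counting with
  the mean-based fruit/vegetable associations;
* energy has no direct association; it acts only through the %E
  recomputation of fats (an optional `energy_bmi` mediation chain exists in
  the association schema but none is shipped enabled).

## Monte Carlo uncertainty

Each association's RR is redrawn from a log-normal with median at the
point estimate and $\sigma_{\log} = (\ln CI_{high} - \ln CI_{low})/(2
\times 1.96)$; draws are independent across associations. The scenario is
re-run per draw and the 5th, 25th, 50th, 75th and 95th percentiles of
deaths averted (linear interpolation between order statistics,
`quantile(type = 7)`) summarise each output key alongside the
deterministic point estimate. Defaults: `n_draws = 2000`, which stabilises
the p5/p95 tails at desk scale.

Two reproducibility mechanisms matter:

* one top-level seed; per-draw sub-seeds are derived by a counter, so
  results do not depend on execution order;
* within one `run_all()`, the *same* RR draws are applied to every label
  (paired comparison), so between-label differences are not blurred by
  sampling noise. Whether published credible intervals shared draws across
  labels is unstated; independent draws are available via
  `common_draws = FALSE`.

## The synthetic-data module

The national inputs this pipeline was designed around (census structure,
cause-of-death registry counts, cohort dietary records) are not
redistributable, so `foplmort` generates structural stand-ins:

* `generate_population()`: a census-like pyramid — near-flat counts with
  small seeded jitter below age 50, exponential decline above, 51.6%
  female share;
* `generate_mortality()`: death rates growing as
  $\exp(\text{gradient} \times \text{bracket index})$ (default gradient
  0.45), a cardiovascular-dominant cause mix with mild stratum-level
  jitter, totals scaled to the configured number of diet-related deaths
  and capped at stratum population;
* `generate_diet()`: stratum means jittered around national targets with a
  linear age trend (default ±5% amplitude, ±2% log-normal jitter), SDs
  from fixed coefficients of variation (0.4 for foods, 0.25 for
  nutrients — plausible nutrition-survey dispersion), and portion
  fractions computed from the same normal model the counterfactual uses.

Default totals are national-scale: 66 million people and 225,000
diet-related NCD deaths (the order implied by a few-thousand averted
deaths being a few percent of the total); the default energy target is the
1976.3 kcal/d reference diet of the worked transposition example and salt
sits at 7.5 g/d. Each generator draws from its own named stream derived
from the seed, so adding one generator never perturbs another's output,
and a fixed seed yields byte-identical tables.

What the synthetic data does *not* emulate: true census and
vital-statistics margins, survey weighting, non-normal intake shapes
(skewed consumption, zero-inflation of fruit intake), correlation between
nutrients within strata, and secular trends. Tests passing on these
fixtures therefore validate the *machinery* — conservation, determinism,
closed-form arithmetic, percentile behaviour, ranking logic — not the
realism of any particular national estimate. Absolute deaths-averted
numbers computed from the fixtures are illustrative only.

## Numerical choices and degenerate inputs

* Quadrature: `stats::integrate` on the standardised scale, limits ±10,
  `rel.tol = 1e-10`; an overflowing RR power raises an error naming the
  association rather than returning `Inf`.
* Zero-SD intakes are handled exactly (degenerate normal); zero death
  counts propagate exactly (a cause with zero baseline deaths averts
  exactly zero).
* Ties: intake exactly at one portion counts as meeting the portion.
* Percentiles use linear interpolation (type 7) so reports are comparable
  across runs and platforms; reports serialise to versioned JSON with full
  double precision.
* Problem sizes used by the test-suite and acceptance run: 36 strata
  (18 brackets × 2 sexes), 7 causes, 13 fixture associations, 2000 Monte
  Carlo draws; the full 6-label × 3-variant sweep at these sizes completes
  in well under two minutes on one core.

## Known limitations

Beyond the static-model caveats above: the purchase-to-intake
transposition assumes household purchases translate proportionally into
individual intakes; label effects estimated in a fully-labelled
experimental catalogue bound, rather than predict, the effect of a
voluntary label; and every absolute number produced with the shipped
association fixture inherits its illustrative status. The engine exposes a
hook for treating portion fractions as an independent risk channel but
ships it disabled, pending a defensible dose-response.

## A minimal run

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 1)
pop <- generate_population(cfg)
mort <- generate_mortality(cfg, pop)
base <- generate_diet(cfg)
report <- run_all(pop, mort, base, read_associations(),
                  n_draws = 2000, seed = 1)
print(report)
summary(report)
plot(report)
```
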
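Package: foplmort
Title: Macro-Simulation of Mortality Impacts of Front-of-Pack Nutrition Labels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative risk assessment pipeline estimating deaths from
    diet-related non-communicable diseases averted or delayed after the
    introduction of a front-of-pack nutrition label (FoPL). Label-induced
    relative differences in purchased nutrient content are transposed onto
    baseline sex- and age-stratified dietary intake distributions to build
    counterfactual "labelled" diets; a PRIME-style log-linear relative-risk
    engine maps the intake shift onto cause-specific mortality, and Monte
    Carlo sampling of the relative risks yields credible intervals.
    Includes a synthetic-data module that generates census-like population
    pyramids, cause-of-death tables and baseline diet distributions so the
    full pipeline is testable without access to restricted national data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
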
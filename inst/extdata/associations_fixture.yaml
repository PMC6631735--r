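# ILLUSTRATIVE DEFAULTS — synthetic fixture.
# The diet–disease relative risks used for substantive national estimates
# come from published meta-analyses and are not redistributed with this
# package. The values below are plausible, fixture-quality defaults in the
# range of that literature, shipped so the full pipeline runs and is
# testable out of the box. Replace this file with a calibrated association
# table before drawing real-world conclusions.
#
# Units: rr applies log-linearly per `unit` of the factor (or, for mediated
# entries, per `unit` of the final mediator). Mediated salt entries act
# through systolic blood pressure: mediation_coeffs holds mmHg per g/d of
# salt; rr is per mmHg.
associations:
  - factor: fruit
    disease: chd
    rr: 0.93
    unit: 106          # g/d
    ci_low: 0.90
    ci_high: 0.96
  - factor: fruit
    disease: stroke
    rr: 0.89
    unit: 106
    ci_low: 0.85
    ci_high: 0.93
  - factor: fruit
    disease: lung_cancer
    rr: 0.95
    unit: 106
    ci_low: 0.91
    ci_high: 0.99
  - factor: vegetable
    disease: chd
    rr: 0.95
    unit: 106
    ci_low: 0.92
    ci_high: 0.98
  - factor: vegetable
    disease: stroke
    rr: 0.94
    unit: 106
    ci_low: 0.90
    ci_high: 0.98
  - factor: fibre
    disease: chd
    rr: 0.91
    unit: 7            # g/d
    ci_low: 0.87
    ci_high: 0.95
  - factor: fibre
    disease: stroke
    rr: 0.93
    unit: 7
    ci_low: 0.88
    ci_high: 0.98
  - factor: fibre
    disease: colorectal_cancer
    rr: 0.90
    unit: 10           # g/d
    ci_low: 0.86
    ci_high: 0.94
  - factor: sfa_pctE
    disease: chd
    rr: 1.04
    unit: 1            # % of total energy
    ci_low: 1.01
    ci_high: 1.07
  - factor: salt
    disease: stroke
    rr: 1.04           # per mmHg SBP
    unit: 1
    ci_low: 1.03
    ci_high: 1.05
    mediation: salt_sbp
    mediation_coeffs: [1.0]   # mmHg SBP per g/d salt
  - factor: salt
    disease: chd
    rr: 1.025
    unit: 1
    ci_low: 1.015
    ci_high: 1.035
    mediation: salt_sbp
    mediation_coeffs: [1.0]
  - factor: salt
    disease: hypertensive_disease
    rr: 1.05
    unit: 1
    ci_low: 1.03
    ci_high: 1.07
    mediation: salt_sbp
    mediation_coeffs: [1.0]
  - factor: salt
    disease: heart_failure
    rr: 1.03
    unit: 1
    ci_low: 1.01
    ci_high: 1.05
    mediation: salt_sbp
    mediation_coeffs: [1.0]
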
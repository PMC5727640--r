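# Base-case configuration: payer-perspective cost-effectiveness model of
# third-line apatinib vs supportive care in metastatic gastric cancer.
# Ranged parameters carry value/low/high; ranges feed the sensitivity
# analyses. Any omitted field takes the same base-case default in code.
schema: 1
config:
  cycle_length_weeks: 1
  horizon_years: 10
  annual_discount_rate: 0.05
  wtp_threshold: 22200        # USD per QALY (3x per-capita GDP)
  currency_year: 2015
utilities:
  u_pfs: {value: 0.88, low: 0.80, high: 0.97}   # progression-free
  u_pd: {value: 0.41, low: 0.28, high: 0.63}    # progressed disease
costs:                         # USD, full charges; payer pays coverage_fraction
  apatinib_unit_cost: {value: 106.5, low: 53.2, high: 106.5}
  unit_strength_mg: 425
  daily_dose_mg: 850
  # per_day: the listed charge buys one treatment-day (reproduces the
  # published cost totals); per_unit: charge per 425 mg tablet, so a day
  # costs (850/425) x unit cost.
  drug_charge_basis: per_day
  supportive_care_per_cycle: {value: 117.1, low: 32.3, high: 322.6}
  end_of_life_palliative: {value: 1483.9, low: 1072.3, high: 2119.3}
  coverage_fraction: {value: 0.60, low: 0.45, high: 0.75}
  pfs_supportive_with_drug: no
pap:
  enabled: yes
  variant: 3+X                 # patients pay the first paid_months of drug
  paid_months: 3
control_pfs: {scale: 0.04191, shape: 1.4165}    # weekly Weibull, control PFS
control_os: {scale: 0.02143, shape: 1.18716}    # weekly Weibull, control OS
hr_pfs: {hr: 0.34, ci_low: 0.27, ci_high: 0.595}
hr_os: {hr: 0.57, ci_low: 0.537, ci_high: 0.937}
budget:
  population: 1000000
  annual_incident_gc_per_million: 215.5
  fraction_advanced: 0.6666666666666666
  fraction_reaching_third_line: 0.7
  uptake_by_year: [0.8, 1, 1, 1, 1]
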
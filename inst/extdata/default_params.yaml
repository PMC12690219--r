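meta:
  currency: USD 2022
  exchange_rate_cny_per_usd: 6.7321
  adherence_scenarios:
  - 0.72
  - 0.54
  version: 0.1.0
discount_rate: 0.05
wtp: 38223.0
wtp_secondary: 50964.0
start_age: 60
max_age: 100
ai_years: 5.0
cancer_transition_fits:
  dfs_to_lrs:
    distribution: lognormal
    params:
      meanlog: 5.33
      sdlog: 2.65
  dfs_to_crs:
    distribution: lognormal
    params:
      meanlog: 7.14
      sdlog: 2.94
  lrs_to_dm:
    distribution: lognormal
    params:
      meanlog: 0.926
      sdlog: 1.373
  crs_to_dm:
    distribution: lognormal
    params:
      meanlog: 1.6
      sdlog: 1.4
  dm_to_death:
    distribution: lognormal
    params:
      meanlog: 0.916
      sdlog: 0.7
fracture_rate_curves:
  hip:
    a: 8.0e-07
    b: 0.1151
  vertebral:
    a: 8.09e-05
    b: 0.0602
  other:
    a: 0.000562
    b: 0.03466
fracture_rate_scale:
  hip: 1.0
  vertebral: 1.0
  other: 1.0
gradient_rr_per_sd:
  hip: 2.6
  vertebral: 1.8
  other: 1.5
rr_subsequent_fracture:
  hip: 2.0
  vertebral: 1.9
  other: 1.8
p_bedridden_after_hip: 0.1
hip_fracture_mortality_hr:
- age: 60.0
  hr: 2.4
- age: 70.0
  hr: 2.1
- age: 80.0
  hr: 1.8
- age: 90.0
  hr: 1.5
background_mortality:
- age: 60.0
  qx: 0.0055
- age: 65.0
  qx: 0.009
- age: 70.0
  qx: 0.015
- age: 75.0
  qx: 0.026
- age: 80.0
  qx: 0.048
- age: 85.0
  qx: 0.09
- age: 90.0
  qx: 0.16
- age: 95.0
  qx: 0.27
- age: 100.0
  qx: 1.0
bmd_baseline:
- age: 60.0
  mean_tscore: -1.2
  sd_tscore: 1.0
- age: 65.0
  mean_tscore: -1.5
  sd_tscore: 1.0
- age: 70.0
  mean_tscore: -1.8
  sd_tscore: 1.0
- age: 75.0
  mean_tscore: -2.1
  sd_tscore: 1.0
bmd_loss_on_ai: 0.12
bmd_loss_natural:
- age: 60.0
  loss: 0.04
- age: 70.0
  loss: 0.05
- age: 80.0
  loss: 0.06
zscore_reference:
- age: 30.0
  mean_tscore: 0.0
  sd_tscore: 1.0
- age: 60.0
  mean_tscore: -1.1
  sd_tscore: 1.0
- age: 65.0
  mean_tscore: -1.4
  sd_tscore: 1.0
- age: 70.0
  mean_tscore: -1.7
  sd_tscore: 1.0
- age: 75.0
  mean_tscore: -2.0
  sd_tscore: 1.0
- age: 80.0
  mean_tscore: -2.3
  sd_tscore: 1.0
- age: 85.0
  mean_tscore: -2.5
  sd_tscore: 1.0
- age: 90.0
  mean_tscore: -2.7
  sd_tscore: 1.0
- age: 95.0
  mean_tscore: -2.8
  sd_tscore: 1.0
young_adult_age: 30
treatment_rr:
  alendronate:
    hip: 0.6
    vertebral: 0.55
    other: 0.8
  denosumab:
    hip: 0.6
    vertebral: 0.32
    other: 0.8
  zoledronate:
    hip: 0.59
    vertebral: 0.3
    other: 0.75
treatment_duration:
  alendronate: 5.0
  denosumab: 5.0
  zoledronate: 3.0
residual_duration:
  alendronate: 5.0
  denosumab: 0.0
  zoledronate: 3.0
adherence: 0.9
risk_modifiers:
  prior_fracture: 1.0
  prior_falls: 2.0
utilities:
  baseline_by_age:
  - age: 60.0
    utility: 0.92
  - age: 70.0
    utility: 0.89
  - age: 80.0
    utility: 0.85
  - age: 90.0
    utility: 0.79
  cancer_state:
    disease_free: 0.95
    locoregional: 0.85
    contralateral: 0.85
    distant_metastasis: 0.68
  fracture_multiplier_first:
    hip: 0.7
    vertebral: 0.79
    other: 0.91
  fracture_multiplier_subsequent:
    hip: 0.9
    vertebral: 0.93
    other: 1.0
  bedridden: 0.28
  fracture_decrement_form: multiplicative
costs:
  drug_annual:
    alendronate: 230.0
    denosumab: 315.0
    zoledronate: 119.0
  dxa: 26.199999999999999
  fracture_acute:
    hip: 5500.0
    vertebral: 3000.0
    other: 1500.0
  fracture_management_annual:
    hip: 297.0
    vertebral: 149.0
    other: 74.0
  long_term_care_annual: 8910.0
  indirect:
    nonmedical_first_year: 1040.0
    caregiver_annual: 5350.0
psa:
- path: p_bedridden_after_hip
  dist: beta
  pars:
    shape1: 13.729251972665603
    shape2: 123.563267753990431
  low: 0.05
  high: 0.15
- path: adherence
  dist: beta
  pars:
    shape1: 17.511725999111004
    shape2: 1.945747333234556
  low: 0.72
  high: 0.98
- path:
  - utilities
  - cancer_state
  - disease_free
  dist: beta
  pars:
    shape1: 84.652880009127031
    shape2: 4.45541473732248
  low: 0.9
  high: 0.99
- path:
  - utilities
  - cancer_state
  - distant_metastasis
  dist: beta
  pars:
    shape1: 35.698431215846817
    shape2: 16.799261748633793
  low: 0.55
  high: 0.8
- path:
  - utilities
  - fracture_multiplier_first
  - hip
  dist: beta
  pars:
    shape1: 24.397531357800549
    shape2: 10.456084867628809
  low: 0.55
  high: 0.85
- path:
  - utilities
  - fracture_multiplier_first
  - vertebral
  dist: beta
  pars:
    shape1: 31.431788316258242
    shape2: 8.355285501790163
  low: 0.65
  high: 0.9
- path:
  - utilities
  - fracture_multiplier_first
  - other
  dist: beta
  pars:
    shape1: 78.617802490030442
    shape2: 7.775387059453557
  low: 0.85
  high: 0.97
- path:
  - utilities
  - bedridden
  dist: beta
  pars:
    shape1: 9.357452041395405
    shape2: 24.062019535016752
  low: 0.15
  high: 0.45
- path:
  - costs
  - dxa
  dist: gamma
  pars:
    shape: 11.719693486563671
    rate: 0.44731654528869
  low: 15.0
  high: 45.0
- path:
  - costs
  - drug_annual
  - alendronate
  dist: gamma
  pars:
    shape: 25.088046274143014
    rate: 0.109078462061491
  low: 150.0
  high: 330.0
- path:
  - costs
  - fracture_acute
  - hip
  dist: gamma
  pars:
    shape: 29.051032789800999
    rate: 0.005282005961782
  low: 3800.0
  high: 7800.0
- path:
  - costs
  - fracture_acute
  - vertebral
  dist: gamma
  pars:
    shape: 26.142253256456712
    rate: 0.008714084418819
  low: 2000.0
  high: 4300.0
- path:
  - costs
  - fracture_acute
  - other
  dist: gamma
  pars:
    shape: 22.126803156264959
    rate: 0.014751202104177
  low: 950.0
  high: 2200.0
- path:
  - costs
  - fracture_management_annual
  - hip
  dist: gamma
  pars:
    shape: 18.592660985472634
    rate: 0.062601552139639
  low: 180.0
  high: 450.0
- path:
  - costs
  - long_term_care_annual
  dist: gamma
  pars:
    shape: 24.895193617486939
    rate: 0.002794073357743
  low: 6000.0
  high: 13000.0
- path:
  - costs
  - indirect
  - caregiver_annual
  dist: gamma
  pars:
    shape: 27.488039207473694
    rate: 0.005137951253733
  low: 3500.0
  high: 7500.0
- path: bmd_loss_on_ai
  dist: gamma
  pars:
    shape: 34.573129931663999
    rate: 288.109416097199983
  low: 0.08
  high: 0.16
- path:
  - fracture_rate_scale
  - hip
  dist: gamma
  pars:
    shape: 50.796150496476031
    rate: 50.796150496476031
  low: 0.75
  high: 1.3
- path:
  - fracture_rate_scale
  - vertebral
  dist: gamma
  pars:
    shape: 50.796150496476031
    rate: 50.796150496476031
  low: 0.75
  high: 1.3
- path:
  - fracture_rate_scale
  - other
  dist: gamma
  pars:
    shape: 50.796150496476031
    rate: 50.796150496476031
  low: 0.75
  high: 1.3
- path:
  - treatment_rr
  - alendronate
  - hip
  dist: lognormal
  pars:
    meanlog: -0.510825623765991
    sdlog: 0.146779263523096
  low: 0.45
  high: 0.8
- path:
  - treatment_rr
  - alendronate
  - vertebral
  dist: lognormal
  pars:
    meanlog: -0.59783700075562
    sdlog: 0.137501632869963
  low: 0.42
  high: 0.72
- path:
  - treatment_rr
  - alendronate
  - other
  dist: lognormal
  pars:
    meanlog: -0.22314355131421
    sdlog: 0.104741773005763
  low: 0.65
  high: 0.98
- path:
  - rr_subsequent_fracture
  - hip
  dist: lognormal
  pars:
    meanlog: 0.693147180559945
    sdlog: 0.149948331934188
  low: 1.5
  high: 2.7

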
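states:
  state:
  - Healthy
  - UndiagnosedDM
  - DiagnosedUntreated
  - OralTherapy
  - InsulinTherapy
  - CombinationTherapy
  - Nephropathy
  - Retinopathy
  - Neuropathy
  - Angina
  - PeripheralVascular
  - MyocardialInfarction
  - Stroke
  - HeartFailure
  - Hyperglycaemia
  - Hypoglycaemia
  - DiabetesDeath
  - OtherDeath
  direct_cost:
  - 0.0
  - 0.0
  - 23.0
  - 185.0
  - 277.0
  - 301.0
  - 1207.0
  - 56.0
  - 6340.0
  - 16.0
  - 16.0
  - 1291.0
  - 2168.0
  - 2493.0
  - 83.0
  - 76.0
  - 0.0
  - 0.0
  oop_cost:
  - 0.0
  - 0.0
  - 13.0
  - 51.0
  - 51.0
  - 51.0
  - 90.0
  - 13.0
  - 13.0
  - 13.0
  - 13.0
  - 90.0
  - 90.0
  - 90.0
  - 90.0
  - 90.0
  - 0.0
  - 0.0
  disability_weight:
  - 0.0
  - 0.049
  - 0.049
  - 0.049
  - 0.049
  - 0.049
  - 1.0
  - 0.184
  - 0.133
  - 0.08
  - 0.014
  - 0.432
  - 0.588
  - 0.179
  - 0.133
  - 0.133
  - 1.0
  - 1.0
complications:
  state:
  - Nephropathy
  - Retinopathy
  - Neuropathy
  - Angina
  - PeripheralVascular
  - MyocardialInfarction
  - Stroke
  - HeartFailure
  - Hyperglycaemia
  - Hypoglycaemia
  untreated_incidence:
  - 0.01
  - 0.021
  - 0.047
  - 0.0067
  - 0.0085
  - 0.017
  - 0.0053
  - 0.0033
  - 0.18
  - 0.18
  therapy_effect:
  - 0.3
  - 0.68
  - 0.94
  - 0.68
  - 0.74
  - 0.61
  - 0.59
  - 0.68
  - 1.0
  - 0.68
cascade:
  p_dx: 0.08
  p_screen: 0.09
  p_dt: 0.3
  p_tna: 0.35
  p_reinit: 0.2
  therapy_effect_mortality: 0.4
econ:
  discount_rate: 0.05
  ce_threshold: 3015.0
  che_thresholds:
  - 0.1
  - 0.25
  - 0.4
  food_poverty_line: 510.0
  cct_diagnosis_amount: 13.0
  cct_treatment_amount: 51.0
  admin_cost_fraction: 0.0
  capacity_floor: 1.0
effect:
  odds_ratio: 1.31
  ci_low: 1.12
  ci_high: 1.54
  or_diagnosis: .na.real
  or_treatment: .na.real
income:
  quintile:
  - 1
  - 2
  - 3
  - 4
  - 5
  lower:
  - 50.0
  - 900.0
  - 1700.0
  - 3200.0
  - 6400.0
  upper:
  - 900.0
  - 1700.0
  - 3200.0
  - 6400.0
  - 40000.0
  shape:
  - 2.0
  - 2.0
  - 2.0
  - 2.0
  - 2.0
  scale:
  - 237.5
  - 650.0
  - 1225.0
  - 2400.0
  - 11600.0
baseline_cascade_split:
  undiagnosed: 0.600600600600601
  diagnosed_untreated: 0.007007007007007
  oral: 0.196196196196196
  insulin: 0.036036036036036
  combination: 0.16016016016016
therapy_split:
  oral: 0.5
  insulin: 0.091836734693878
  combination: 0.408163265306122
prevalence_targets:
- 0.175
- 0.184
- 0.2
- 0.22
- 0.24
female_share: 0.5
female_incidence_ratio: 1.3
horizon_years: 45
cycle_length: 1
pop_per_quintile: 6000000.0
screening_transfers: yes
treatment_boosts_initiation: yes
net_cct_from_oop: yes
discount_dalys: yes
synthesis:
  seed: 20201
  jitter_sd: 0.03
  inc_floor: 0.002
  inc_ceiling: 0.02
  inc_midage: 50.0
  inc_age_scale: 8.0
  bg_base: 0.002
  bg_growth: 0.075
  bg_sex_ratio: 1.25
  dm_mort_base: 0.035
  dm_mort_growth: 0.045
  dm_mort_quintile_ratio: 1.1
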
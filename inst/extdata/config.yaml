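arms:
  in_person:
    p_success: 0.96
    components:
    - label: Compensation
      payer: health_system
      kind: fixed
      amount: 103.74
    - label: Equipment
      payer: health_system
      kind: fixed
      amount: 2.16
    - label: Drugs
      payer: health_system
      kind: variable
      amount: 0.21
    - label: Other (linens)
      payer: health_system
      kind: variable
      amount: 3.83
    - label: Clinical assistant (10 min)
      payer: health_system
      kind: variable
      amount: 10.25
    - label: Surgeon fee
      payer: health_system
      kind: variable
      amount: 43.46
    - label: Resident
      payer: health_system
      kind: variable
      amount: 10.56
    - label: Patient leisure time
      payer: patient
      kind: variable
      amount: 102.24
    - label: Caregiver wage
      payer: patient
      kind: variable
      amount: 33.84
    - label: Travel (to and from clinic)
      payer: patient
      kind: variable
      amount: 38.11
    - label: Parking
      payer: patient
      kind: variable
      amount: 32.8
  mobile:
    p_success: 0.96
    components:
    - label: Health centre setup
      payer: health_system
      kind: fixed
      amount: 1.39
    - label: Design/setup procedure protocols
      payer: health_system
      kind: fixed
      amount: 6.94
    - label: Staff training
      payer: health_system
      kind: fixed
      amount: 0.44
    - label: Platform licensing, accounts
      payer: health_system
      kind: variable
      amount: 42.0
    - label: Standard support
      payer: health_system
      kind: variable
      amount: 43.05
    - label: Infrastructure hosting
      payer: health_system
      kind: variable
      amount: 19.95
    - label: Surgeon fee
      payer: health_system
      kind: variable
      amount: 22.0
econ_params:
  wtp_per_qaly: 109970.0
  qaly_loss_per_complication: 0.04
  exchange_rate_usd_per_cad: 0.9102
  visits_per_month: 1.64
  clinic_hours_per_visit: 1.0
  leisure_hours_per_visit: 3.0
  caregiver_hourly_wage: 11.28
  parking_per_visit: 20.0
  travel_cost_per_km: 0.15288029525
  amortization_years: 5.0
  patients_per_year: 1000.0
  data_mb_per_submission: 0.35
  data_price_per_gb: 22.5
psa:
  n_draws: 10000
  seed: 20140922
  clinic_cost_rel_halfwidth: 0.2
  effect_abs_halfwidth: 0.02
  wage_mean: 20.780487804878
  wage_cv: 0.4
cohort:
  'n': 1000
  seed: 76
  distance_mean: 76.0
  distance_sdlog: 0.7
  distance_cap: 540.0
  wage_mean: 23.95
  wage_cv: 0.35
  participation_rate: 0.75
  homemaker_wage: 11.28
  mean_visits: 1.64
  complication_rate: 0.05
  caregiver_rate: 1.0
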
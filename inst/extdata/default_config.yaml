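start_age: 58.100000000000001
horizon_age: 100.0
smr_y1:
  value: 5.21
  lo: 4.25
  hi: 6.38
smr_y2plus:
  value: 1.74
  lo: 1.42
  hi: 2.13
rr_mortality:
  value: 1.03
  lo: 0.92
  hi: 1.16
risk28:
  deaths: 548
  'n': 5981
utility_survivor:
  value: 0.735
  lo: 0.7
  hi: 0.77
utility_decrements:
  under65: 0.0
  age65_74: 0.02
  age75plus: 0.07
discount_rate_costs: 0.035
discount_rate_qalys: 0.035
wtp_threshold: 20000.0
trial_curve:
  shape: geometric
  ratio: 0.9
half_cycle_correction: yes
resource_use:
  txa:
    total_los:
      mean: 5.83
      se: 1.46
    icu_days:
      mean: 0.4
      se: 0.46
    procedures:
      endoscopy_diagnostic:
        k: 4781
        'n': 5953
      endoscopy_therapeutic:
        k: 2542
        'n': 5953
      surgery:
        k: 146
        'n': 5953
      radiology_diagnostic:
        k: 1704
        'n': 5953
      radiology_therapeutic:
        k: 74
        'n': 5953
    transfusions:
      blood:
        k: 3984
        'n': 5951
        mean_units: 2.8
        se_units: 0.61
      ffp:
        k: 910
        'n': 5951
        mean_units: 0.9
        se_units: 0.61
      platelets:
        k: 219
        'n': 5951
        mean_units: 0.2
        se_units: 0.23
  no_txa:
    total_los:
      mean: 5.8
      se: 1.47
    icu_days:
      mean: 0.4
      se: 0.51
    procedures:
      endoscopy_diagnostic:
        k: 4729
        'n': 5978
      endoscopy_therapeutic:
        k: 2658
        'n': 5978
      surgery:
        k: 158
        'n': 5978
      radiology_diagnostic:
        k: 1744
        'n': 5978
      radiology_therapeutic:
        k: 89
        'n': 5978
    transfusions:
      blood:
        k: 4018
        'n': 5978
        mean_units: 2.9
        se_units: 0.69
      ffp:
        k: 993
        'n': 5978
        mean_units: 1.0
        se_units: 0.66
      platelets:
        k: 255
        'n': 5978
        mean_units: 0.2
        se_units: 0.26
unit_costs:
  bed_day_nonicu: 338.0
  bed_day_icu: 1594.0
  endoscopy_diagnostic: 665.0
  endoscopy_therapeutic: 777.0
  surgery: 1377.0
  radiology_diagnostic: 4986.0
  radiology_therapeutic: 4986.0
  blood_unit: 132.0
  ffp_unit: 31.0
  platelets_unit: 192.0
txa_admin_components:
  drug: 12.0
  needle: 0.05
  syringe: 0.07
  infusion_bag: 0.59
  isotonic_solution: 2.96
  nurse_time: 14.35
postdischarge_costs:
  year1: 4350.0
  year2: 1980.0
  year3: 1938.0
  year4plus_fraction: 0.333333333333333
psa:
  'n': 10000
  cost_se_fraction: 0.5
  seed: 1
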
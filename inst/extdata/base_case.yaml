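scenario: base_case
pap: no
discount: 0.05
wtp: 212676.0
utilities:
  pf: 0.901
  pd: 0.863
grid:
  first_cycle_days: 14.0
  later_cycle_days: 28.0
  phase_switch_months: 12.0
  horizon_months: 480.0
conventions:
  gengamma_shape: negated
  half_cycle: no
  pps_clock: since_progression
arms:
  durvalumab:
    ttp:
      family: gengamma
      params:
        beta: 0.6323
        sigma: 0.648
        k: 7.3951
      source: table1
    pfs:
      family: gengamma
      params:
        beta: 0.6478
        sigma: 0.6448
        k: 6.9943
      source: table1
    pps:
      family: lognormal
      params:
        meanlog: 3.0448
        sdlog: 1.1876
      source: table1
  bsc:
    ttp:
      family: gengamma
      params:
        beta: 0.6384
        sigma: 0.5739
        k: 4.2698
      source: table1
    pfs:
      family: gengamma
      params:
        beta: 0.6274
        sigma: 0.5416
        k: 4.0697
      source: table1
    pps:
      family: lognormal
      params:
        meanlog: 3.0448
        sdlog: 1.1876
      source: table1
treatment:
  dose_per_kg: 10.0
  body_weight: 61.200000000000003
  frequency_days: 14.0
  max_duration_months: 12.0
  vials:
    sizes_mg:
    - 120.0
    - 500.0
    price_params:
    - price_durvalumab_120
    - price_durvalumab_500
pap_schedule:
  stage1_paid: 2.0
  stage1_free: 2.0
  stage2_paid: 4.0
costs:
  pf_monthly: 800.0
  pd_monthly: 1200.0
  terminal: 20000.0
  ae_entry:
    durvalumab: 0.0
    bsc: 0.0
  subsequent:
  - label: immunotherapy
    proportion: 0.25
    items:
    - param: price_nivolumab_100
      units_per_month: 4.3
  - label: targeted
    proportion: 0.25
    items:
    - param: price_erlotinib_box
      units_per_month: 4.3
  - label: chemotherapy
    proportion: 0.3
    items:
    - param: price_pemetrexed_500
      units_per_month: 2.9
    - param: price_carboplatin_100
      units_per_month: 6.5
  - label: radiotherapy
    proportion: 0.2
    items:
    - param: price_imrt
      units_per_month: 0.02
  source: placeholder
psa:
  'n': 1000.0
params:
- name: price_durvalumab_120
  base: 6066.0
  se: 606.600000000000023
  low: 4935.539999999999964
  high: 7311.289999999999964
  dist: gamma
- name: price_durvalumab_500
  base: 18088.0
  se: 1808.799999999999955
  low: 14717.1200000000008
  high: 21801.279999999998836
  dist: gamma
- name: price_nivolumab_40
  base: 4587.0
  se: 458.699999999999989
  low: 3732.170000000000073
  high: 5528.659999999999854
  dist: gamma
- name: price_nivolumab_100
  base: 9250.0
  se: 925.0
  low: 7526.170000000000073
  high: 11148.930000000000291
  dist: gamma
- name: price_pembrolizumab_100
  base: 17918.0
  se: 1791.799999999999955
  low: 14578.799999999999272
  high: 21596.380000000001019
  dist: gamma
- name: price_docetaxel_20
  base: 302.399999999999977
  se: 30.239999999999998
  low: 246.039999999999992
  high: 364.480000000000018
  dist: gamma
- name: price_vinorelbine_10
  base: 126.900000000000006
  se: 12.69
  low: 103.25
  high: 152.949999999999989
  dist: gamma
- name: price_erlotinib_box
  base: 1275.75
  se: 127.579999999999998
  low: 1038.0
  high: 1537.650000000000091
  dist: gamma
- name: price_crizotinib_box
  base: 15600.0
  se: 1560.0
  low: 12692.780000000000655
  high: 18802.520000000000437
  dist: gamma
- name: price_afatinib_box
  base: 1400.0
  se: 140.0
  low: 1139.099999999999909
  high: 1687.410000000000082
  dist: gamma
- name: price_gemcitabine_1g
  base: 787.720000000000027
  se: 78.769999999999996
  low: 640.919999999999959
  high: 949.42999999999995
  dist: gamma
- name: price_carboplatin_100
  base: 53.899999999999999
  se: 5.39
  low: 43.859999999999999
  high: 64.969999999999999
  dist: gamma
- name: price_cisplatin_30
  base: 19.149999999999999
  se: 1.92
  low: 15.58
  high: 23.079999999999998
  dist: gamma
- name: price_paclitaxel_100
  base: 533.42999999999995
  se: 53.340000000000003
  low: 434.019999999999982
  high: 642.940000000000055
  dist: gamma
- name: price_pemetrexed_500
  base: 2776.9699999999998
  se: 277.699999999999989
  low: 2259.449999999999818
  high: 3347.050000000000182
  dist: gamma
- name: price_3dcrt
  base: 30000.0
  se: 3000.0
  low: 24409.200000000000728
  high: 36158.680000000000291
  dist: gamma
- name: price_imrt
  base: 50000.0
  se: 5000.0
  low: 40682.0
  high: 60264.470000000001164
  dist: gamma
- name: price_igimrt
  base: 80000.0
  se: 8000.0
  low: 65091.190000000002328
  high: 96423.160000000003492
  dist: gamma
- name: price_tomo
  base: 100000.0
  se: 10000.0
  low: 81363.990000000005239
  high: 120528.94999999999709
  dist: gamma
- name: utility_pf
  base: 0.901
  se: 0.009
  low: 0.883
  high: 0.918
  dist: beta
- name: utility_pd
  base: 0.863
  se: 0.009
  low: 0.845
  high: 0.88
  dist: beta
- name: discount
  base: 0.05
  se: .na.real
  low: 0.0
  high: 0.08
  dist: uniform
- name: age
  base: 62.899999999999999
  se: 0.34
  low: 62.240000000000002
  high: 63.560000000000002
  dist: normal
- name: weight
  base: 61.200000000000003
  se: 0.74
  low: .na.real
  high: .na.real
  dist: fixed
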
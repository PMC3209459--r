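start_age: 5
horizon: 25
discount_rate: 0.035
anchors:
  age:
  - 3
  - 8
  - 16
  proportion:
  - 1.0
  - 0.6
  - 0.5
cost_bands:
  sector:
  - nhs
  - nhs
  - nhs
  - social_services
  - social_services
  - social_services
  - education
  - education
  - education
  - voluntary
  - voluntary
  - voluntary
  age_lo:
  - 5.0
  - 11.0
  - 17.0
  - 5.0
  - 11.0
  - 17.0
  - 5.0
  - 11.0
  - 17.0
  - 5.0
  - 11.0
  - 17.0
  age_hi:
  - 10.0
  - 16.0
  - .na.real
  - 10.0
  - 16.0
  - .na.real
  - 10.0
  - 16.0
  - .na.real
  - 10.0
  - 16.0
  - .na.real
  annual_cost:
  - 1113.0
  - 101.0
  - 101.0
  - 157.0
  - 63.0
  - 63.0
  - 882.0
  - 1202.0
  - 0.0
  - 23.0
  - 23.0
  - 23.0
cost_spec:
  group_median: 952.0
  individual_median: 2078.0
  group_share: 0.8
scenarios:
  base:
    dropout: 0.44
    effectiveness: 0.34
    recidivism: 0.5
  best:
    dropout: 0.06
    effectiveness: 0.68
    recidivism: 0.0
  worst:
    dropout: 0.6
    effectiveness: 0.2
    recidivism: 0.5
provision_mixes:
- 1.0
- 0.8
- 0.0
crime:
  schedule_csv: ~
  calibrate: yes
  targets:
    criminal_justice: 2842.0
    victim: 7468.0
    lost_output: 2197.0
    other: 906.0
  peak_age: 18.0
  scale: 60000.0
  noise_sd: 0.1
seed: 1
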
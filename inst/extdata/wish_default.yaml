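# Default WISH index definition. Thresholds in g/day.
# Edit a copy of this file and pass it via wish_index(path = ...) or
# `wish ... --config` for a locally adapted index.
components:
- id: whole_grains
  health_class: protective
  env_class: low
  lower: 100.0
  recommended: 125.0
  shape: ramp_up_open
  upper: 150.0
- id: vegetables
  health_class: protective
  env_class: low
  lower: 200.0
  recommended: 300.0
  shape: ramp_up_open
  upper: 600.0
- id: fruits
  health_class: protective
  env_class: low
  lower: 100.0
  recommended: 200.0
  shape: ramp_up_open
  upper: 300.0
- id: dairy
  health_class: protective
  env_class: medium
  lower: 0.0
  recommended: 250.0
  shape: optimum_band
  upper: 500.0
- id: red_meat
  health_class: limit
  env_class: high
  lower: 0.0
  recommended: 14.0
  shape: ramp_down
  upper: 28.0
- id: fish
  health_class: protective
  env_class: high
  lower: 0.0
  recommended: 28.0
  shape: optimum_band
  upper: 100.0
- id: eggs
  health_class: neutral
  env_class: medium
  lower: 0.0
  recommended: 13.0
  shape: ramp_down
  upper: 25.0
- id: poultry
  health_class: neutral
  env_class: medium
  lower: 0.0
  recommended: 29.0
  shape: ramp_down
  upper: 58.0
- id: legumes
  health_class: protective
  env_class: low
  lower: 0.0
  recommended: 75.0
  shape: ramp_up_open
  upper: 100.0
- id: nuts
  health_class: protective
  env_class: medium
  lower: 0.0
  recommended: 50.0
  shape: optimum_band
  upper: 75.0
- id: unsat_oils
  health_class: protective
  env_class: low
  lower: 20.0
  recommended: 40.0
  shape: ramp_up_capped
  upper: 80.0
- id: sat_oils
  health_class: limit
  env_class: high
  lower: 0.0
  recommended: 11.8
  shape: bivariate_limit
  upper: 11.8
- id: added_sugars
  health_class: limit
  env_class: low
  lower: 0.0
  recommended: 31.0
  shape: bivariate_limit
  upper: 31.0
subscores:
  healthy:
  - whole_grains
  - vegetables
  - fruits
  - dairy
  - fish
  - eggs
  - poultry
  - legumes
  - nuts
  - unsat_oils
  less_healthy:
  - red_meat
  - sat_oils
  - added_sugars
  low_env:
  - whole_grains
  - vegetables
  - fruits
  - legumes
  - unsat_oils
  - added_sugars
  high_env:
  - sat_oils
  - dairy
  - red_meat
  - fish
  - eggs
  - poultry
  - nuts
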
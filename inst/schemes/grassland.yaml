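kind: grassland
label: Grassland degradation index (six-criterion weighted sum)
aggregation: weighted_sum
# DI <= 30 natural, 31-64 semi-degraded, >= 65 degraded
cutpoints: [30.0, 65.0]
criteria:
- name: proximity_to_localities
  attribute: dist_locality_km
  mode: band
  direction: lower_is_worse
  thresholds: [2.0, 4.0]   # >4 km natural, 2-4 semi, <2 degraded
  weight: 5.0
  domain: [0.0, 10.0]
- name: proximity_to_sheepfolds
  attribute: dist_sheepfold_km
  mode: band
  direction: lower_is_worse
  thresholds: [0.5, 2.0]   # >2 km natural, 0.5-2 semi, <0.5 degraded
  weight: 20.0
  domain: [0.0, 8.0]
- name: slope
  attribute: slope_deg
  mode: band
  direction: higher_is_worse
  thresholds: [15.0, 30.0]  # <15 natural, 15-30 semi, >30 degraded
  weight: 5.0
  domain: [0.0, 90.0]
- name: livestock_density_deviation
  attribute: livestock_dev_pct
  mode: band
  direction: higher_is_worse
  thresholds: [10.0, 30.0]  # on |deviation|
  weight: 10.0
  domain: [-200.0, 200.0]
  transform: abs
- name: invasive_species
  attribute: invasive_pct
  mode: band
  direction: higher_is_worse
  thresholds: [5.0, 20.0]   # <5 natural, 5-20 semi, >20 degraded
  weight: 50.0
  domain: [0.0, 100.0]
- name: bare_soil_erosion
  attribute: bare_soil_pct
  mode: band
  direction: higher_is_worse
  thresholds: [5.0, 20.0]
  weight: 100.0
  domain: [0.0, 100.0]
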
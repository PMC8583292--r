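kind: river
label: River multicriteria assessment (13 criteria in 4 classes)
aggregation: weighted_sum
# weights are normalized (sum 1); aggregate in [0, 2]
# The six highest-importance criteria (anthropization, riparian vegetation
# cover, major pollution sources, transport network, riverbank
# interventions, ecological status) carry double weight; the numeric
# values are package stand-ins, overridable in this file.
cutpoints: [0.5, 1.5]
criteria:
# A. human pressure on riparian areas
- name: anthropization
  attribute: anthropization_pct
  direction: higher_is_worse
  thresholds: [33.0, 66.0]
  weight: 0.10526316
  domain: [0.0, 100.0]
- name: riparian_vegetation_cover
  attribute: riparian_veg_pct
  direction: lower_is_worse
  thresholds: [40.0, 70.0]
  weight: 0.10526316
  domain: [0.0, 100.0]
- name: human_settlements
  attribute: settlement_pct
  direction: higher_is_worse
  thresholds: [33.0, 66.0]
  weight: 0.05263158
  domain: [0.0, 100.0]
- name: sewage_treatment_plants
  attribute: sewage_plant_density
  direction: higher_is_worse
  thresholds: [0.5, 2.0]
  weight: 0.05263158
  domain: [0.0, 10.0]
- name: major_pollution_sources
  attribute: pollution_source_density
  direction: higher_is_worse
  thresholds: [0.5, 2.0]
  weight: 0.10526316
  domain: [0.0, 10.0]
- name: transport_network
  attribute: transport_km_per_km
  direction: higher_is_worse
  thresholds: [0.5, 1.5]
  weight: 0.10526316
  domain: [0.0, 10.0]
- name: protected_areas
  attribute: protected_area_pct
  direction: lower_is_worse
  thresholds: [10.0, 50.0]
  weight: 0.05263158
  domain: [0.0, 100.0]
# B. substrate of adjacent land
- name: slope
  attribute: slope_deg
  direction: higher_is_worse
  thresholds: [15.0, 30.0]
  weight: 0.05263158
  domain: [0.0, 90.0]
- name: soil_permeability
  attribute: soil_permeability_class
  direction: lower_is_worse
  thresholds: [2.0, 4.0]
  weight: 0.05263158
  domain: [1.0, 6.0]
# C. indicators associated with rivers
- name: riverbank_interventions
  attribute: intervention_pct
  direction: higher_is_worse
  thresholds: [10.0, 40.0]
  weight: 0.10526316
  domain: [0.0, 100.0]
- name: ecological_status
  attribute: ecological_status_class
  direction: higher_is_worse
  thresholds: [2.0, 3.0]
  weight: 0.10526316
  domain: [1.0, 5.0]
- name: dam_density
  attribute: dam_density
  direction: higher_is_worse
  thresholds: [0.2, 1.0]
  weight: 0.05263158
  domain: [0.0, 5.0]
# D. morphological complexity
- name: sinuosity
  attribute: sinuosity
  direction: lower_is_worse
  thresholds: [1.1, 1.3]
  weight: 0.05263158
  domain: [1.0, 3.0]
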
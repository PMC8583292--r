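kind: coastal
label: Coastal assessment, terrestrial zone (eight summed indicators)
aggregation: weighted_sum
# indicator sum <= 4 natural, 5-12 semi-degraded, >= 13 degraded
cutpoints: [4.0, 13.0]
criteria:
- name: invasive_species
  attribute: invasive_pct
  direction: higher_is_worse
  thresholds: [5.0, 20.0]
  weight: 1.0
  domain: [0.0, 100.0]
- name: wastewater_treatment
  attribute: wastewater_plants
  direction: higher_is_worse
  thresholds: [1.0, 3.0]
  weight: 1.0
  domain: [0.0, 20.0]
- name: demographic_poles
  attribute: demographic_poles
  direction: higher_is_worse
  thresholds: [1.0, 3.0]
  weight: 1.0
  domain: [0.0, 20.0]
- name: shoreline_artificialization
  attribute: shoreline_artificial_pct
  direction: higher_is_worse
  thresholds: [10.0, 40.0]
  weight: 1.0
  domain: [0.0, 100.0]
- name: shoreline_erosion
  attribute: erosion_rate_m_yr
  direction: higher_is_worse
  thresholds: [0.5, 2.0]
  weight: 1.0
  domain: [0.0, 20.0]
- name: road_infrastructure
  attribute: road_km_per_km2
  direction: higher_is_worse
  thresholds: [0.5, 2.0]
  weight: 1.0
  domain: [0.0, 10.0]
- name: navigation_channels
  attribute: navigation_channels
  direction: higher_is_worse
  thresholds: [1.0, 2.0]
  weight: 1.0
  domain: [0.0, 10.0]
- name: maritime_traffic
  attribute: traffic_intensity
  direction: higher_is_worse
  thresholds: [33.0, 66.0]
  weight: 1.0
  domain: [0.0, 100.0]
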
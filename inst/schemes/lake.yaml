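kind: lake
label: Lake composite index (wastewater-recreation-agriculture-size-
  transport-industry-cover pollutant load with vulnerability)
aggregation: weighted_sum
# eight unit-weight banded components, aggregate in [0, 16]
cutpoints: [4.0, 12.0]
criteria:
- name: wastewater
  attribute: wastewater_score
  direction: higher_is_worse
  thresholds: [33.0, 66.0]
  weight: 1.0
  domain: [0.0, 100.0]
- name: recreation
  attribute: recreation_score
  direction: higher_is_worse
  thresholds: [33.0, 66.0]
  weight: 1.0
  domain: [0.0, 100.0]
- name: agriculture
  attribute: agriculture_score
  direction: higher_is_worse
  thresholds: [33.0, 66.0]
  weight: 1.0
  domain: [0.0, 100.0]
- name: size
  attribute: size_score
  direction: higher_is_worse
  thresholds: [33.0, 66.0]
  weight: 1.0
  domain: [0.0, 100.0]
- name: transportation
  attribute: transport_score
  direction: higher_is_worse
  thresholds: [33.0, 66.0]
  weight: 1.0
  domain: [0.0, 100.0]
- name: industry
  attribute: industry_score
  direction: higher_is_worse
  thresholds: [33.0, 66.0]
  weight: 1.0
  domain: [0.0, 100.0]
- name: land_cover
  attribute: cover_score
  direction: higher_is_worse
  thresholds: [33.0, 66.0]
  weight: 1.0
  domain: [0.0, 100.0]
- name: vulnerability
  attribute: vulnerability_score
  direction: higher_is_worse
  thresholds: [33.0, 66.0]
  weight: 1.0
  domain: [0.0, 100.0]
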
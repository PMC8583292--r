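kind: cave
label: Cave conservation index (impact + vulnerability form totals)
aggregation: weighted_sum
# CCI 0-34 natural, 35-84 semi-degraded, >= 85 degraded
cutpoints: [34.0, 85.0]
criteria:
- name: environmental_impact
  attribute: impact_score
  mode: raw        # pre-aggregated rapid-assessment form total
  weight: 1.0
  domain: [0.0, 100.0]
- name: vulnerability
  attribute: vulnerability_score
  mode: raw        # pre-aggregated vulnerability form total
  weight: 1.0
  domain: [0.0, 100.0]
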
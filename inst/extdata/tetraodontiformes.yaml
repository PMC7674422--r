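# Example calibration configuration: the pufferfish order with two candidate
# first records, the older one down-weighted relative to the younger.
clades:
  - label: Tetraodontiformes
    tips: [takifugu, mola]
    fossils:
      - {name: Cretatriacanthus, age_min: 83.0, age_max: 89.8, weight: 0.6666666666666666}
      - {name: Plectocretacicus, age_min: 98.0, age_max: 100.3, weight: 0.3333333333333333}
bd:
  net_diversification: [0.041, 0.081]
  turnover: [0.0011, 0.37]
  sampling_rate: [0.0066, 0.01806]
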
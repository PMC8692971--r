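{
  "paramuricea_clavata": {
    "allometric_a": 0.002,
    "allometric_b": 2.61,
    "size_bins_cm": [10, 20, 30, 40],
    "affected_threshold_pct": 10,
    "sublethal_temp_c": 23,
    "lethal_temp_c": 25
  },
  "corallium_rubrum": {
    "allometric_a": 0.1535,
    "allometric_b": 1.9732,
    "size_bins_cm": [3, 6, 9, 15],
    "affected_threshold_pct": 10,
    "sublethal_temp_c": 23,
    "lethal_temp_c": 25
  }
}
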
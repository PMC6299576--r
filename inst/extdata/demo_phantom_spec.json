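{
  "shape": [64, 64, 64],
  "spacing": [3, 3, 3],
  "lesion_fraction": 0.08,
  "lesion_bias_lower": 0.8,
  "seed": 20260928,
  "cohort": {
    "n": 6,
    "f_range": [0, 0.15],
    "intercept": 100,
    "slope": 300,
    "noise_sd": 5,
    "seed": 20260928
  }
}
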
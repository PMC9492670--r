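{
  "mode": "synthetic",
  "harmonization": "zscore",
  "k": 5,
  "holdout_fraction": 0.25,
  "seed": 42,
  "synthetic": {
    "n_controls": 36,
    "n_patients": 24,
    "n_sites": 3,
    "n_regions": 8,
    "delta_years": 4,
    "seed": 42,
    "noise_sd": 0.022677
  }
}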
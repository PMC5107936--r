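{
  "group_a": {
    "name": "CD",
    "n_regions": 68,
    "n_modules": 4,
    "r_within": 0.35,
    "r_between": 0.1,
    "hub_regions": [17, 68],
    "r_hub": 0.35,
    "mean_thickness": 2.5,
    "sd_thickness": 0.25
  },
  "group_b": {
    "name": "HC",
    "n_regions": 68,
    "n_modules": 4,
    "r_within": 0.5,
    "r_between": 0.1,
    "hub_regions": [1, 34],
    "r_hub": 0.35,
    "mean_thickness": 2.5,
    "sd_thickness": 0.25
  }
}
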
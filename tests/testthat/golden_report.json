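{
  "state_proportions": {
    "behavior": ["traveling", "foraging", "resting"],
    "mean_pct": [0, 51.7857142857, 48.2142857143],
    "sd_pct": [0, 0, 0],
    "mean_prop": [0, 0.51785714286, 0.48214285714],
    "sd_prop": [0, 0, 0],
    "n_individuals": [1, 1, 1]
  },
  "depth_summary": {
    "behavior": ["traveling", "foraging", "resting"],
    "mu_mean": [12.4866458027, 208.6269486548, 10.6915277507],
    "mu_lower": [0.48306985505, 182.4238594823, 0.83493612596],
    "mu_upper": [27.63747224, 234.9229349465, 19.310439869],
    "q25": ["NA", 171.1731694379, 15.4824313344],
    "q75": ["NA", 229.8103203327, 29.1142016267],
    "max_depth": ["NA", 359.8484186482, 46.8622036514],
    "n_dives": [0, 29, 27]
  },
  "deep_dives": {
    "total": 0,
    "by_behavior": [0, 0, 0]
  }
}
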
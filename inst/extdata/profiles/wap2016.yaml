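# Canonical profile: West Antarctic Peninsula 2016 study conditions.
paths:
  data_dir: data
  out_dir: out
interval_hours: 6
filters:
  max_speed_kmh: 20
  max_gap_h: 12
  min_span_h: 24
  min_dive_depth_m: 10
  min_dive_duration_s: 20
mcmc:
  n_chains: 2
  n_iter: 30000
  n_burnin: 28000
  thin: 4
  seed: 1
simulate:
  n_animals: 11
  steps_per_animal: 107
  fixes_per_interval_rate: 7.9
  dives_per_interval_rate: 22.4
  missing_interval_prob: 0.1
  seed: 1
report:
  n_uncertainty_draws: 50
  deep_dive_threshold_m: 400
verbose: false
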
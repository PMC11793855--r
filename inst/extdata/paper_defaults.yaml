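# Operating point of the published system, spelled out explicitly.
# Identical to neoperf::default_config(); kept as a checked-in profile so
# runs can pin and archive their configuration.
protocol:
  n_cycles: 3
  threshold_frac: 0.5
  debounce_s: 0.25
  baseline_s: 3
  nominal_press_s: 5
  nominal_release_s: 10
  tolerance_frac: 0.2
mbll:
  source_detector_cm: 1.0
  baseline_s: 1
windows:
  baseline_s: 3
  press_plateau_s: 2
  recovery_plateau_s: 3
  rate_fit_s: 2
rbfnn:
  n_hidden: 64
  threshold: 0.5
  mu: 0.05
  epochs: 200
split:
  policy: subject
  n_train: 70
  n_test: 30
sim:
  sampling_rate: 20
  press_s: 5
  release_s: 10
  n_cycles: 3
  trials_per_subject: 6
seed: 1
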
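# Small demonstration pipeline configuration: one healthy layer-IV cell group
# responding to the naturalistic contact stimulus at 10 amplitudes.
seed: 1
simulate:
  cells:
    - layer: IV
      condition: sham
      stimulus: contact
      nUnits: 12
      p0: 0.25
      p1: 0.25
      p2: 0.25
      p3: 0.25
  timing:
    a: 10
    b: 1
    sigma: 1.5
  n_intensities: 10
  n_trials: 20
  baseline_rate: 5
analysis:
  window_ms: 50
  bin_ms: 1
  merge_gap: 5
  min_support: 9
  unit_wide_max: yes
  peakiness_variant: literal
  t_test_variant: pooled
  k_paths: 3
  epsilon: 0.001
  alpha: [0.05, 0.01]
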
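scenario: tight_rotating
model:
  beta_bar: 37.2
  chi: 83.3
  v_r: 100.0
  v_a: 0.0
  ell: 5.0
  response_mode: minimal
  dt: 1.0e-3
signal:
  kind: exponential
  S0: 1.0
  S1: 0.025
  axis: [1.0, 0.0]
ensemble:
  'N': 37
  n_traj: 100
  T: 50.0
  window: [12.5, 50.0]
  seed: 1
  snapshot_dt: 0.1
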
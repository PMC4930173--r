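scenario: rotation_sweep
model:
  beta_bar: 35.0
  chi: 0.0
  v_r: 100.0
  v_a: 0.0
  ell: 5.0
  response_mode: minimal
  dt: 1.0e-3
signal:
  kind: uniform
  S0: 1.0
ensemble:
  'N': 37
  n_traj: 10
  T: 25.0
  seed: 1
  snapshot_dt: 0.1
grid:
  chi: [5.0, 20.0, 35.0, 50.0, 65.0, 80.0, 95.0]
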
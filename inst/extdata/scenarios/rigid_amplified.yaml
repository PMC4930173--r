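scenario: rigid_amplified
model:
  beta_bar: 0.2
  v_r: 500.0
  v_a: 500.0
  chi: 0.0
  response_mode: legi_switch
  lam: 0.01
  dt: 1.0e-4
  legi: {kA: 5.0, k_mA: 5.0, kI: 1.0, k_mI: 1.0, kR: 0.05, k_mR: 50.0, kD: 4.0}
signal:
  kind: exponential
  S0: 1.0
  S1: 0.025
  axis: [1.0, 0.0]
ensemble:
  'N': 19
  n_traj: 20
  T: 6.0
  seed: 1
  snapshot_dt: 0.1
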
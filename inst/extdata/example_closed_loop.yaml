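variant: closed_loop
H0: 0.5
seed: 7
method: rk4
grid:
  from: 0.0
  to: 20.0
  by: 0.1
params:
  alpha_r: 1.0
  kappa: 0.5
  beta: 0.5
  lam_total: 10.0
  gamma_sens: -1.0
  C0: 1.0
  delta_sc: 0.2
  eta: 0.5
drivers:
  S: 1.0
  P: 0.5
  E_env: 0.5
  R_exo: 1.0
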
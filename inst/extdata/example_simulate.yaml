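variant: linear
H0: 0.0
seed: 7
method: rk4
grid:
  from: 0.0
  to: 10.0
  by: 0.1
params:
  alpha1: 0.5
  alpha2: 0.3
  alpha3: 0.2
  beta: 0.1
drivers:
  S: 1.0
  P: 0.5
  E_env: 0.5
  C_exo: 1.0
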
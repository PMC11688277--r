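budget: 9.0
seed: 1
individuals:
  - {a: 1.0, b: 1.0, theta: 1.0, delta_u: 1.0}
  - {a: 1.5, b: 0.5, theta: 0.8, delta_u: 0.8}
  - {a: 0.8, b: 0.3, theta: 0.9, delta_u: 0.9}
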
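window: 12
z_drop: -2.0
z_rise: 2.0
escalation_levels: [2.0, 3.0, 4.0]
baseline_window: 48
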
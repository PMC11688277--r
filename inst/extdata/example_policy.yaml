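max_gap: 5
kernel_scale: 5.0
noise_sd: 0.0
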
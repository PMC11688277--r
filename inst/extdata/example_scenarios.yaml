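scenarios:
  - name: community_care
    benefit: {E_h: 10.0, E_s: 5.0, E_e: 2.0, w_h: 0.5, w_s: 0.3, w_e: 0.2}
    cost: {C_d: 3.0, C_o: 4.0, C_m: 2.0, w_d: 2.0, w_o: 1.0, w_m: 0.5}
  - name: home_care
    benefit: {E_h: 8.0, E_s: 6.0, E_e: 3.0}
    cost: {C_d: 2.0, C_o: 3.0, C_m: 1.0}
  - name: hospital_care
    benefit: {E_h: 12.0, E_s: 3.0, E_e: 4.0}
    cost: {C_d: 6.0, C_o: 5.0, C_m: 3.0}
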
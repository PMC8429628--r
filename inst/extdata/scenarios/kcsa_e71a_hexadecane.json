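{
  "name": "kcsa_e71a_hexadecane",
  "description": "KcsA(E71A) in POPE-POPG / n-hexadecane bilayer; conductance from the published I-V fit, kinetics are synthetic defaults",
  "conductance_g": 127.6,
  "reversal_E": 0,
  "open_prob": 0.85,
  "mean_open": 100,
  "channel_count_lambda": 0.6
}
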
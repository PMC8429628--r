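{
  "name": "kcsa_wt_tea",
  "description": "KcsA(WT) with 10 mM TEA; block modeled as reduced apparent conductance, kinetics are synthetic defaults",
  "conductance_g": 52.2,
  "reversal_E": 0,
  "open_prob": 0.10,
  "mean_open": 20,
  "channel_count_lambda": 0.6
}
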
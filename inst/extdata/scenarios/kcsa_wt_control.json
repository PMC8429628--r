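{
  "name": "kcsa_wt_control",
  "description": "KcsA(WT), no blocker; conductance from the published control I-V fit, kinetics are synthetic defaults",
  "conductance_g": 90.2,
  "reversal_E": 0,
  "open_prob": 0.10,
  "mean_open": 20,
  "channel_count_lambda": 0.6
}
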
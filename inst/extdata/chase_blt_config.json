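{
  "workflow": "simulate_sf",
  "scheme": "dissociation_chase",
  "rates": {
    "k_minus1": 0.12,
    "k_minus2": 0.002
  },
  "sigma": 0.02,
  "seed": 1
}
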
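{
  "n": 10,
  "heterogeneity_sd": 0.5,
  "seed": 1
}
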
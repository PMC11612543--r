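{
  "SSf": 0.978,
  "SMf": 0.855,
  "SLf": 0.859,
  "HSf": 0.449,
  "SSm": 0.962,
  "SMm": 0.777,
  "SLm": 0.904,
  "HSm": 0.511,
  "HMm": 0.541,
  "HLm": 0.789,
  "G_Mf": 0.879,
  "G_Lf": 0.569,
  "G_Mm": 0.747,
  "G_Lm": 0.678,
  "G_juvMf": 0.4,
  "G_juvMm": 0.4,
  "s0": 0.75,
  "K_M": 5,
  "K_L": 6
}
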
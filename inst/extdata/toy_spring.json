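{
  "a": 1,
  "b": 1,
  "D": 1,
  "x0": 0.1,
  "t_end": 1,
  "dt": 0.001,
  "seed": 1
}
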
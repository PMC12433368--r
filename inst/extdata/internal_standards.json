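{
  "aT1": 2.0,
  "aT3": 10.0,
  "bT1": 5.0,
  "bT2": 5.0,
  "gT10": 0.5,
  "dT2": 0.2,
  "zT8": 0.1
}
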
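{
  "EX_glc": -9.4,
  "EX_xyl": 0,
  "EX_etoh": 2.7,
  "EX_ac": 2
}
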
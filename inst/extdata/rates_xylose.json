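{
  "EX_glc": 0,
  "EX_xyl": -5,
  "EX_etoh": 0,
  "EX_ac": 0
}
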
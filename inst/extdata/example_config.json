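{
  "_comment": "example vsdgate CLI config; values act as flag defaults (CLI flags override)",
  "variant": "WT",
  "steps": 21,
  "step-size": 0.5,
  "cutoff": 4.5,
  "seed": 7,
  "preset": "WT",
  "protocol": "iv"
}
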
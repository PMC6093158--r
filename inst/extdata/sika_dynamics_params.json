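{
  "phi0": -0.04,
  "phi_d": 5.94,
  "phi_h": 0.50,
  "gam0": -1.34,
  "gam_d": 8.28,
  "gam_h": 0.64
}
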
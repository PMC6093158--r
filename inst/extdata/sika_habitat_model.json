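{
  "formula": {
    "include_lu": true,
    "climate": "scp",
    "include_topo": true,
    "autocov": null
  },
  "coefficients": {
    "intercept": 1.236,
    "scp": -0.036,
    "rgn_other": -6.511,
    "scp_x_rgn": 0.020,
    "fr": 4.273,
    "ws": 3.623,
    "ag": 5.264,
    "ag2": -3.061,
    "bt": -2.894,
    "sl": 0.115
  }
}
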
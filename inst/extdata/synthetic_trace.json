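{
  "schema_version": "1.0",
  "d_um": 28.4,
  "k_clv_nN_per_um": 3,
  "condition": "CTRL",
  "seed": 42,
  "package_version": "0.1.0",
  "truth": {
    "params": {
      "T0": 7.44,
      "k1": 3.23,
      "k2": 10.94,
      "eta": 7.85
    }
  }
}
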
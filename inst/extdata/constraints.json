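{
  "bounds": {
    "R1": {
      "ub": 2
    },
    "R2": {
      "lb": -1
    }
  }
}
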
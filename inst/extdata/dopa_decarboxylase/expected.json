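{
  "L_columns": {
    "l1": [1, 0, 1, 0],
    "l2": [1, 0, 0, 1],
    "l3": [0, 1, 1, 0]
  },
  "compositions": {
    "l1": [8, 11, 1, 2],
    "l2": [1, 2],
    "l3": 1
  }
}
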
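{
  "L_columns": {
    "l1": [1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0],
    "l2": [1, 1, 1, 0, 1, 1, 0, 0, 0, 0, 0],
    "l3": [0, 0, 0, 0, 0, 0, 1, 1, 0, 0, 0],
    "l4": [0, 0, 0, 1, 0, 0, 1, 0, 0, 1, 1],
    "l5": [0, 0, 0, 0, 0, 1, 1, 0, 0, 1, 0],
    "l6": [0, 1, 2, 2, 0, 0, 0, 0, 1, 0, 0],
    "l7": [0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 0]
  },
  "n_moieties": 7,
  "compositions": {
    "l1": [8, 11, 1],
    "l2": [1, 2],
    "l3": [9, 13, 5, 3],
    "l4": 1,
    "l5": 1
  },
  "p": 170,
  "q": 176,
  "n_components": 57,
  "classes": ["transitive", "transitive", "internal", "integrative", "integrative", "transitive", "transitive"]
}
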
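{
  "metabolites": [
    {
      "id": "L-DOPA",
      "name": "levodopa",
      "formula": {
        "C": 9,
        "H": 11,
        "N": 1,
        "O": 4
      },
      "charge": 0
    },
    {
      "id": "H+",
      "name": "hydrogen ion",
      "formula": {
        "H": 1
      },
      "charge": 1
    },
    {
      "id": "DA",
      "name": "dopamine",
      "formula": {
        "C": 8,
        "H": 12,
        "N": 1,
        "O": 2
      },
      "charge": 1
    },
    {
      "id": "CO2",
      "name": "carbon dioxide",
      "formula": {
        "C": 1,
        "O": 2
      },
      "charge": 0
    }
  ],
  "reactions": [
    {
      "id": "R1",
      "kind": "internal",
      "stoichiometry": {
        "L-DOPA": -1,
        "H+": -1,
        "DA": 1,
        "CO2": 1
      }
    },
    {
      "id": "E1",
      "kind": "exchange",
      "stoichiometry": {
        "L-DOPA": 1
      }
    },
    {
      "id": "E2",
      "kind": "exchange",
      "stoichiometry": {
        "H+": 1
      }
    },
    {
      "id": "E3",
      "kind": "exchange",
      "stoichiometry": {
        "DA": -1
      }
    },
    {
      "id": "E4",
      "kind": "exchange",
      "stoichiometry": {
        "CO2": -1
      }
    }
  ]
}
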
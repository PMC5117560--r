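{
  "metabolites": [
    {
      "id": "Phe",
      "name": "L-phenylalanine",
      "formula": {
        "C": 9,
        "H": 11,
        "N": 1,
        "O": 2
      },
      "charge": 0
    },
    {
      "id": "Tyr",
      "name": "L-tyrosine",
      "formula": {
        "C": 9,
        "H": 11,
        "N": 1,
        "O": 3
      },
      "charge": 0
    },
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
    },
    {
      "id": "Formate",
      "name": "formate",
      "formula": {
        "C": 1,
        "H": 1,
        "O": 2
      },
      "charge": -1
    },
    {
      "id": "BH4",
      "name": "tetrahydrobiopterin",
      "formula": {
        "C": 9,
        "H": 15,
        "N": 5,
        "O": 3
      },
      "charge": 0
    },
    {
      "id": "BH2",
      "name": "dihydrobiopterin",
      "formula": {
        "C": 9,
        "H": 13,
        "N": 5,
        "O": 3
      },
      "charge": 0
    },
    {
      "id": "O2",
      "name": "dioxygen",
      "formula": {
        "O": 2
      },
      "charge": 0
    },
    {
      "id": "H2O",
      "name": "water",
      "formula": {
        "H": 2,
        "O": 1
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
    }
  ],
  "reactions": [
    {
      "id": "R1",
      "kind": "internal",
      "stoichiometry": {
        "Phe": -1,
        "Tyr": 1,
        "BH4": -1,
        "BH2": 1,
        "O2": -1,
        "H2O": 1
      }
    },
    {
      "id": "R2",
      "kind": "internal",
      "stoichiometry": {
        "Tyr": -1,
        "L-DOPA": 1,
        "BH4": -1,
        "BH2": 1,
        "O2": -1,
        "H2O": 1
      }
    },
    {
      "id": "R3",
      "kind": "internal",
      "stoichiometry": {
        "L-DOPA": -1,
        "DA": 1,
        "CO2": 1,
        "H+": -1
      }
    },
    {
      "id": "R4",
      "kind": "internal",
      "stoichiometry": {
        "CO2": 1,
        "Formate": -1,
        "BH4": 1,
        "BH2": -1,
        "H+": -1
      }
    },
    {
      "id": "E1",
      "kind": "exchange",
      "stoichiometry": {
        "O2": 1
      }
    },
    {
      "id": "E2",
      "kind": "exchange",
      "stoichiometry": {
        "Phe": 1
      }
    },
    {
      "id": "E3",
      "kind": "exchange",
      "stoichiometry": {
        "H2O": -1
      }
    },
    {
      "id": "E4",
      "kind": "exchange",
      "stoichiometry": {
        "DA": -1
      }
    },
    {
      "id": "E5",
      "kind": "exchange",
      "stoichiometry": {
        "CO2": -1
      }
    },
    {
      "id": "E6",
      "kind": "exchange",
      "stoichiometry": {
        "Formate": 1
      }
    },
    {
      "id": "E7",
      "kind": "exchange",
      "stoichiometry": {
        "H+": 1
      }
    }
  ]
}
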
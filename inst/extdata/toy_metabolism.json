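{
  "reactions": {
    "EX_glc": {
      "glc": 1
    },
    "EX_lcts": {
      "lcts": 1
    },
    "LCTShyd": {
      "lcts": -1,
      "glc": 1.9
    },
    "GLYC": {
      "glc": -1,
      "prec": 1
    }
  },
  "bounds": {
    "EX_glc": [0, 10],
    "EX_lcts": [0, 10]
  },
  "objective": {
    "prec": 1
  },
  "exchange_reactions": ["EX_glc", "EX_lcts"],
  "exchange_species": {
    "EX_glc": "glc_e",
    "EX_lcts": "lcts_e"
  },
  "molecular_weights": {
    "glc": 0.18,
    "lcts": 0.342,
    "prec": 0.18
  }
}
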
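{
  "species": [
    "DNA",
    "DNA.P2",
    "mRNA",
    "P",
    "P2"
  ],
  "reactions": [
    {
      "name": "R1",
      "reactants": {
        "DNA": 1,
        "P2": 1
      },
      "products": {
        "DNA.P2": 1
      },
      "rate_law": "mass_action",
      "theta": 0.1
    },
    {
      "name": "R2",
      "reactants": {
        "DNA.P2": 1
      },
      "products": {
        "DNA": 1,
        "P2": 1
      },
      "rate_law": "mass_action",
      "theta": 0.7
    },
    {
      "name": "R3",
      "reactants": {
        "DNA": 1
      },
      "products": {
        "DNA": 1,
        "mRNA": 1
      },
      "rate_law": "mass_action",
      "theta": 0.35
    },
    {
      "name": "R4",
      "reactants": {
        "mRNA": 1
      },
      "products": {},
      "rate_law": "mass_action",
      "theta": 0.3
    },
    {
      "name": "R5",
      "reactants": {
        "P": 2
      },
      "products": {
        "P2": 1
      },
      "rate_law": "mass_action",
      "theta": 0.1
    },
    {
      "name": "R6",
      "reactants": {
        "P2": 1
      },
      "products": {
        "P": 2
      },
      "rate_law": "mass_action",
      "theta": 0.9
    },
    {
      "name": "R7",
      "reactants": {
        "mRNA": 1
      },
      "products": {
        "mRNA": 1,
        "P": 1
      },
      "rate_law": "mass_action",
      "theta": 0.2
    },
    {
      "name": "R8",
      "reactants": {
        "P": 1
      },
      "products": {},
      "rate_law": "mass_action",
      "theta": 0.1
    }
  ],
  "convention": "binomial",
  "conserved": [
    {
      "species": ["DNA", "DNA.P2"],
      "total": 10
    }
  ]
}
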
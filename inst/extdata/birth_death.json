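{
  "species": [
    "A"
  ],
  "reactions": [
    {
      "name": "R1",
      "reactants": {
        "A": 1
      },
      "products": {},
      "rate_law": "mass_action",
      "theta": 0.03
    },
    {
      "name": "R2",
      "reactants": {},
      "products": {
        "A": 1
      },
      "rate_law": "mass_action",
      "theta": 0.6
    }
  ],
  "convention": "binomial"
}
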
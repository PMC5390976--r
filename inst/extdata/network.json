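{
  "metabolites": [
    {
      "id": "A",
      "external": false
    }
  ],
  "reactions": [
    {
      "id": "R1",
      "stoich": {
        "A": "1"
      },
      "reversible": false
    },
    {
      "id": "R2",
      "stoich": {
        "A": "-1"
      },
      "reversible": true
    },
    {
      "id": "R3",
      "stoich": {
        "A": "-1"
      },
      "reversible": false
    }
  ]
}
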
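{
  "metadata": {
    "record": "synthetic-example-001",
    "specimen": "demo"
  },
  "genotypes": [
    { "gene": "CYP2D6", "value": "*1/*2", "note": "reported by external lab" },
    { "gene": "CYP2C19", "value": "*1/*2" },
    { "gene": "CYP2C9", "value": "*1/*3" },
    { "gene": "VKORC1", "value": "-1639G>A A/G" },
    { "gene": "HLA-B", "value": "*57:01 negative" }
  ],
  "current_medications": ["paroxetine", "rifampin"],
  "considered_medications": ["codeine", "warfarin", "abacavir"]
}
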
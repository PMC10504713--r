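{
  "shanghai_totals.csv": "2bc950f8dab46f8cff0e33c8cf739391",
  "shanghai_elderly.csv": "742a459945f503a6f30c4136cea9aa3b",
  "shanghai_age_structure.csv": "087af5207aaa1ccb808955cbf7a2ce56"
}
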
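[
  {
    "name": "glycine",
    "smiles": "NCC(=O)O",
    "database": "CID",
    "id": "750"
  },
  {
    "name": "alanine",
    "smiles": "N[C@@H](C)C(=O)O",
    "database": "CID",
    "id": "602"
  },
  {
    "name": "ornithine",
    "smiles": "N[C@@H](CCCN)C(=O)O",
    "database": "CID",
    "id": "6262"
  },
  {
    "name": "N-acetyl-isoleucine",
    "smiles": "CC(=O)N[C@@H]([C@@H](C)CC)C(=O)O",
    "database": "CID",
    "id": "306133"
  },
  {
    "name": "putrescine",
    "smiles": "NCCCCN",
    "database": "CID",
    "id": "1045"
  },
  {
    "name": "roseotoxin A",
    "formula": "C31H53N5O7",
    "database": "CID",
    "id": "161158"
  },
  {
    "name": "roseotoxin A isomer (synthetic decoy)",
    "formula": "C31H53N5O7",
    "database": "MSB",
    "id": "decoy-1"
  }
]
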
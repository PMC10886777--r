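{
  "_comment": "Interaction-capable site templates for the 20 standard amino acids. Backbone typing (N donor when an amide H is present, O acceptor with neighbor C; PRO has no amide donor) is applied in code to every residue. 'donors' lists side-chain heavy atoms whose attached hydrogens (found geometrically, < 1.3 A) form donor pairs. 'acceptors' lists side-chain acceptor atoms with their bonded heavy neighbors. 'ring' entries are aromatic systems. Formal charges are fixed template values (no pKa modeling): LYS +1, ARG +1, ASP -1, GLU -1; HIS is treated neutral. Hydrophobes are the carbon/sulfur side-chain atoms of the apolar residues.",
  "ALA": { "hydrophobes": ["CB"] },
  "ARG": {
    "donors": ["NE", "NH1", "NH2"],
    "cations": [{ "atoms": ["NE", "CZ", "NH1", "NH2"], "charge": 1 }]
  },
  "ASN": {
    "donors": ["ND2"],
    "acceptors": [{ "atom": "OD1", "neighbors": ["CG"] }]
  },
  "ASP": {
    "acceptors": [
      { "atom": "OD1", "neighbors": ["CG"] },
      { "atom": "OD2", "neighbors": ["CG"] }
    ],
    "anions": [{ "atoms": ["OD1", "OD2"], "charge": -1 }]
  },
  "CYS": { "hydrophobes": ["CB", "SG"] },
  "GLN": {
    "donors": ["NE2"],
    "acceptors": [{ "atom": "OE1", "neighbors": ["CD"] }]
  },
  "GLU": {
    "acceptors": [
      { "atom": "OE1", "neighbors": ["CD"] },
      { "atom": "OE2", "neighbors": ["CD"] }
    ],
    "anions": [{ "atoms": ["OE1", "OE2"], "charge": -1 }]
  },
  "GLY": {},
  "HIS": {
    "donors": ["ND1", "NE2"],
    "acceptors": [
      { "atom": "ND1", "neighbors": ["CG", "CE1"] },
      { "atom": "NE2", "neighbors": ["CD2", "CE1"] }
    ],
    "rings": [["CG", "ND1", "CD2", "CE1", "NE2"]]
  },
  "ILE": { "hydrophobes": ["CB", "CG1", "CG2", "CD1"] },
  "LEU": { "hydrophobes": ["CB", "CG", "CD1", "CD2"] },
  "LYS": {
    "donors": ["NZ"],
    "cations": [{ "atoms": ["NZ"], "charge": 1 }]
  },
  "MET": { "hydrophobes": ["CB", "CG", "SD", "CE"] },
  "PHE": {
    "rings": [["CG", "CD1", "CD2", "CE1", "CE2", "CZ"]],
    "hydrophobes": ["CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"]
  },
  "PRO": { "hydrophobes": ["CB", "CG", "CD"] },
  "SER": {
    "donors": ["OG"],
    "acceptors": [{ "atom": "OG", "neighbors": ["CB"] }]
  },
  "THR": {
    "donors": ["OG1"],
    "acceptors": [{ "atom": "OG1", "neighbors": ["CB"] }]
  },
  "TRP": {
    "donors": ["NE1"],
    "rings": [
      ["CG", "CD1", "NE1", "CE2", "CD2"],
      ["CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"]
    ],
    "hydrophobes": ["CB", "CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"]
  },
  "TYR": {
    "donors": ["OH"],
    "acceptors": [{ "atom": "OH", "neighbors": ["CZ"] }],
    "rings": [["CG", "CD1", "CD2", "CE1", "CE2", "CZ"]],
    "hydrophobes": ["CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"]
  },
  "VAL": { "hydrophobes": ["CB", "CG1", "CG2"] }
}
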
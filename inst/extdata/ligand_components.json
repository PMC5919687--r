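{
  "comment": "Curated chemical component codes driving ligand moiety flags. adenosine_phosphate: nucleotide ligands carrying an adenosine phosphate substructure. amino_acid: free amino-acid ligands. aminoacyl_adenylate: activated amino-acid-AMP intermediates and close analogues, which set both flags.",
  "adenosine_phosphate": ["ATP", "ADP", "AMP", "ANP", "ACP", "AGS", "APC", "A", "AN2", "SAP"],
  "amino_acid": ["ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"],
  "aminoacyl_adenylate": ["TYM", "TSB", "LSA", "GSU", "P5A", "VMS", "5CA", "QSI", "HSS", "DSA", "N0B", "1HA"]
}
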
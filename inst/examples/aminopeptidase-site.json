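{
  "description": "Five-residue di-zinc coordination site of bovine lens leucine aminopeptidase (Lys, Asp, Asp, Asp, Glu). With five residues the ten pair constraints are pruned to the four edges of the minimum spanning tree.",
  "reference": "1lap.cif",
  "assembly": "1",
  "numbering": "auth",
  "selectors": ["A-250", "A-255", "A-273", "A-332", "A-334"],
  "parameters": { "tolerance": 1, "rmsd_cutoff": 2.0, "atom_mode": "sidechain" }
}
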
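{
  "description": "Simplified His2/Cys2 zinc-finger query (Cys, His, His) from a zinc-finger/DNA complex. The fourth residue of the classical motif is omitted: its backbone sits in a flexible loop and makes the four-residue query overly strict.",
  "reference": "1g2f.cif",
  "assembly": "1",
  "numbering": "auth",
  "selectors": ["F-207", "F-225", "F-229"],
  "parameters": { "tolerance": 1, "rmsd_cutoff": 2.0, "atom_mode": "sidechain" }
}
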
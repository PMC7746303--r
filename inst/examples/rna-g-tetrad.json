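{
  "description": "RNA G-tetrad: four guanines joined by Hoogsteen pairing in a quadruplex. Substitute the selectors with the four guanines of one tetrad plane of your reference entry (shown here for a telomeric RNA quadruplex); nucleotides use C4'/C1' as representatives.",
  "reference": "3mij.cif",
  "assembly": "1",
  "numbering": "auth",
  "selectors": ["A-4", "A-5", "A-10", "A-11"],
  "parameters": { "tolerance": 1, "rmsd_cutoff": 2.0, "atom_mode": "sidechain" }
}
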
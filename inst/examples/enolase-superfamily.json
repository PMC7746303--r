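{
  "description": "Enolase-superfamily catalytic motif from mandelate racemase with position-specific exchanges: Lys/His at the first and last positions, Glu/Asp/Asn at the fourth. Exchanges multiply the descriptor keys read per edge.",
  "reference": "2mnr.cif",
  "assembly": "1",
  "numbering": "auth",
  "selectors": ["A-164", "A-195", "A-221", "A-247", "A-297"],
  "exchanges": { "1": ["H"], "4": ["D", "N"], "5": ["K"] },
  "parameters": { "tolerance": 1, "rmsd_cutoff": 2.0, "atom_mode": "sidechain" }
}
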
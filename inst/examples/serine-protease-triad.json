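{
  "description": "His-Asp-Ser catalytic triad of bovine alpha-chymotrypsin; the canonical serine-protease active site, split across two polypeptide chains of the mature enzyme.",
  "reference": "4cha.cif",
  "assembly": "1",
  "numbering": "auth",
  "selectors": ["B-57", "B-102", "C-195"],
  "parameters": { "tolerance": 1, "rmsd_cutoff": 2.0, "atom_mode": "sidechain" }
}
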
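Package: strucmotif
Title: Real-Time Structural Motif Search with an Inverted Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Index-accelerated search for small three-dimensional motifs
    (catalytic sites, metal-coordination sites, base tetrads) in corpora of
    macromolecular structures. Residue pairs are summarised by a
    rotation-invariant geometric descriptor (backbone distance, sidechain
    distance, inter-vector angle) binned and stored in a word-level inverted
    index, so that all occurrences of a query motif can be retrieved,
    assembled per structure, and scored by quaternion-based least-squares
    RMSD without scanning coordinate files. Supports mmCIF and legacy PDB
    input, biological-assembly expansion, position-specific residue
    exchanges, nucleotide motifs, incremental index updates, and a synthetic
    structure generator with planted motif instances for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    bio3d,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'chemdata.R'
    'geometry.R'
    'AllClasses.R'
    'AllGenerics.R'
    'mmcif.R'
    'structures.R'
    'select.R'
    'descriptors.R'
    'store.R'
    'index.R'
    'search.R'
    'scoring.R'
    'synthetic.R'
    'cli.R'
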
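---
title: "Inverted-index structural motif search: methods and design notes"
author: "strucmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverted-index structural motif search: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strucmotif)
```

# The problem

A structural motif is a small set of residues — typically three to six — in a
characteristic three-dimensional arrangement: a catalytic triad, a
metal-coordination shell, a base tetrad. Motifs may span several polymer
chains and be far apart in sequence, so sequence search does not find them,
and naive 3D search must consider every combination of $k$ residues in every
structure of a corpus. This package implements an index-accelerated approach:
almost all of the geometric work is done once, at indexing time, and a query
then touches only the handful of index bins its own geometry selects.
Candidate structures are identified *without opening any coordinate file*;
coordinates are read only for the few residues of each surviving candidate,
and each candidate is scored by least-squares superposition RMSD.

# Residue representation

Every polymer residue is reduced to two representative points:

* amino acids — the C$\alpha$ atom (backbone) and the C$\beta$ atom
  (sidechain). Glycine has no C$\beta$; a virtual one is reconstructed by
  least-squares superposition of an ideal L-alanine fragment (N, CA, C) onto
  the glycine backbone, transplanting the alanine C$\beta$. The
  reconstruction is equivariant under rigid motion and places the virtual
  atom ~1.53 Å from C$\alpha$.
* nucleotides — C4′ (backbone) and C1′ (sidechain).

Two points per residue deliberately flatten the differences between residue
types: a tryptophan and an alanine become comparable, which is what makes
position-specific exchanges meaningful. Residue-type tokens are upper-case
one-letter amino-acid codes plus lower-case `a c g t u` for nucleotides, so
alanine and adenosine never collide. Modified components are translated to
their parent token by a configurable table (`defaultModifiedMap()`;
phosphoserine counts as serine); unmapped components are excluded and
counted in the load report.

# The pair descriptor

For an unordered residue pair the package measures three rigid-motion
invariants (see `pairGeometry()`):

* $d_b$ — distance between the two backbone representatives (Å),
* $d_s$ — distance between the two sidechain representatives (Å),
* $\theta$ — angle between the two backbone→sidechain vectors (degrees,
  $[0, 180]$).

Distances are binned at 1 Å, angles at 20°, with left-closed intervals and a
floor convention ($d_b \in [8,9) \rightarrow$ bin 8; $\theta = 180°$ clamps
into bin 8). Together with the lexicographically sorted token pair this
yields a descriptor key such as `HS-8-7-5` — a histidine/serine pair with
$d_b \in [8,9)$ Å, $d_s \in [7,8)$ Å, $\theta \in [100,120)°$, the
signature geometry of the serine-protease catalytic triad. Keys pack
bijectively into a single integer, strictly monotone in
(type pair, $d_b$ bin, $d_s$ bin, $\theta$ bin); see `encodeKey()`.

```{r descriptor}
motif <- syntheticTriadMotif()
g <- pairGeometry(motif[[1]], motif[[3]])
unlist(g)
renderKey(binDescriptor("H", "S", g))
```

Whether the original formulation floors or rounds at bin borders is not
something the rendered key alone can disambiguate in general; the floor
convention is the simplest one consistent with the worked `HS-8-7-5`
example, and the calibration test pins it.

# The inverted index

`enumeratePairs()` lists every unordered residue pair with $d_b < 20$ Å —
intra- and inter-chain, across assembly copies. The 20 Å cutoff comfortably
covers common motifs while bounding index size; motifs may still be larger
than 20 Å overall as long as a spanning set of their pairs is admissible.
`buildIndex()` writes one file per descriptor bin (packed key under a
type-pair fan-out directory), mapping structure identifiers to sorted
occurrence lists. An occurrence is the pair of residue locators
`<label_asym_id>_<operator>-<label_seq_id>` (e.g. `A_1-87`), so hits in any
copy of a biological assembly are first-class. Chain and operator tokens
are interned per bin and occurrences stored as flat integer arrays.

Each occurrence also carries an orientation flag recording which of its two
(locator-ordered) residues bears the first token of the sorted type pair;
without it, a retrieved `HS` occurrence could not be mapped onto "role 2 is
the histidine" during assembly.

Builds stage into a temporary directory and publish by a single rename; the
JSON manifest carries a checksum over the logical content so a torn write
is detected on open. `updateIndex()` performs incremental loads (and
replacements) whose result is bin-for-bin identical to a fresh build of the
union corpus — the property that makes periodic archive updates safe.

The coordinate store solves a different problem: scoring needs a handful of
residues from each candidate, and parsing whole structure files back in
would dominate the runtime. Each structure gets a small locator→offset
table plus a flat binary record file; `fetchResidues()` seeks directly to
the requested records. Stored coordinates are rounded to 0.1 Å, which has a
negligible effect on RMSDs (it bounds a self-match at roughly 0.05 Å
rather than 0) while keeping records small. Full precision is kept in
memory during parsing and query definition; only the store rounds.

# Queries, pruning, assembly

`defineQuery()` takes a reference structure plus residue selectors (label
or author numbering) and optional per-role exchanges; each role allows its
own token plus the exchange tokens. All pairwise geometries are measured in
the reference; pairs at $d_b \ge 20$ Å are inadmissible, and the graph of
admissible pairs must connect all roles.

With $n \ge 4$ roles, the $n(n-1)/2$ pair constraints are pruned to the
$n-1$ edges of the minimum spanning tree (Kruskal; edge weight = reference
$d_b$; deterministic tie-break by role-index pair). Fewer edges mean fewer
bin reads and — because every retained constraint must be satisfied —
*fewer* false rejections; the constraints are mutually redundant, so the
tree keeps candidates connected while cycles are validated later by the
RMSD stage. Geometry distorted in an omitted pair simply scores a high
RMSD and is filtered by the cutoff; the package does not re-check omitted
pairs before coordinate retrieval. The $d_b$ weight was chosen because it
is computable at query time without corpus statistics; weighting edges by
bin rarity instead would read smaller postings and is noted as future work.

At search time each edge expands into descriptor keys: one per combination
of the two roles' allowed tokens, each surrounded by its tolerance
neighborhood (`neighborKeys()`; tolerance $t$ consults up to $(2t+1)^3$
bins per token combination, clamped at range edges). Tolerance 1 — three
bins per measure — is the default: it guarantees that two geometries
separated only by a bin border still find each other. Structures missing
postings for *any* edge are rejected outright. For the survivors an exact
backtracking join over the roles (in an edge order where each new edge
touches an already-bound role) enumerates every injective role→locator
assignment consistent with all retained edges. The suite checks this
assembly against a brute-force enumeration that ignores the index
entirely, across randomized corpora and tolerances 0–2.

# Scoring

Atom correspondence is by name intersection, per role: `all` pairs every
shared heavy-atom name, `sidechain` (the default) restricts to non-backbone
names, `representatives` uses exactly the two representative points. When
an exchange matched, only the shared names pair (a Lys against a His
contributes N, CA, C, O, CB, CG); no attempt is made to resolve chemically
ambiguous labels such as the two ring branches of a tyrosine. The default
is `sidechain` because all-atom superposition over-weights backbone
geometry when chain directions differ; every result records the mode used.

Superposition uses the quaternion eigenvalue method: the optimal proper
rotation is the largest eigenvector of the 4×4 quaternion key matrix. The
minimised RMSD is evaluated from the residuals under that rotation rather
than from the $\sqrt{g - 2\lambda_{max}}$ shortcut, which cancels
catastrophically for near-identical sets (the residual form is exact to
~1e-15 at zero, the shortcut only to ~1e-7). The suite cross-checks
against an independent SVD (Kabsch) implementation. Hits are sorted by
RMSD with full deterministic tie-breaks, so repeated runs are
byte-identical.

No statistical significance is attached to hits: a sound null model for
"this arrangement arose by chance" is an open problem, and the RMSD plus
expert inspection of the aligned site remains the honest interface.

# The synthetic generator

Real archive data cannot be bundled, so validation rests on a generator
(`generateStructure()`, `plantMotif()`, `makeBenchmarkCorpus()`) that
emulates exactly the features the method consumes:

* C$\alpha$ positions on a self-avoiding random walk with the canonical
  3.8 Å virtual bond (minimum non-neighbor separation 3.4 Å);
* per-residue backbone atoms (N, CA, C, O, CB) from a randomly oriented
  ideal-alanine fragment, so the glycine reconstruction path is exercised
  by construction, with the sidechain representative ~1.53 Å from
  C$\alpha$ in a random direction;
* schematic sidechain atoms marching along the C$\alpha$→C$\beta$
  direction, carrying the correct standard atom names per residue type;
* residue types uniform over the 20 amino acids;
* corpora written as genuine mmCIF, so every test exercises the parser.

Planting substitutes motif residues at chosen positions under a random
rigid transform, then adds independent Gaussian noise per atom coordinate
(σ in Å, applied after the transform — the simplest model that exercises
bin-boundary behavior). The generator does **not** emulate Ramachandran
statistics, sterics beyond self-avoidance, secondary structure, real
sidechain rotamers, or crystallographic artefacts. Passing tests therefore
demonstrate the correctness of the indexing/retrieval/scoring machinery —
equivalence with exhaustive search, recall under controlled noise — not
biological sensitivity on real archives, which additionally depends on how
real motif variability compares with the bin widths.

A packaged synthetic catalytic-triad-like motif (`syntheticTriadMotif()`)
places His/Asp/Ser with the His–Ser pair at $d_b = 8.45$ Å,
$d_s \approx 7.6$ Å, $\theta = 105°$ — the canonical serine-protease
range — and anchors the binning calibration; its coordinates are
constructed from ideal fragments, not taken from any archive entry.

# Parameters at a glance

| Parameter | Default | Units | Notes |
|---|---|---|---|
| indexing cutoff on $d_b$ | 20 | Å | pairs at or beyond are not indexed |
| distance bin width | 1 | Å | floor convention, left-closed |
| angle bin width | 20 | ° | 9 bins; 180° clamps down |
| $d_s$ bin ceiling | 31 | bin | packing bound; larger pairs skipped with a count |
| tolerance | 1 | bins/measure | $(2t+1)^3$ bins per edge token combination |
| RMSD cutoff | none (CLI examples use 1–2) | Å | sub-1 Å is the conventional "biologically meaningful" range |
| atom mode | `sidechain` | — | `all`, `representatives` selectable |
| stored precision | 0.1 | Å | coordinate store only; in-memory full precision |
| assembly | `"1"` | — | `"asym"` for the asymmetric unit |

# Numerical and degenerate-input choices

* Zero-length backbone→sidechain vectors (coincident representatives) are
  a degenerate-geometry error for a single pair and a counted skip during
  enumeration.
* Collinear N/CA/C glycine backbones cannot orient the reconstruction and
  error out; during loading such residues are excluded and counted.
* Superposition requires ≥ 3 pairs and non-collinear point sets.
* $\theta = 180°$ exactly clamps into bin 8 rather than opening a tenth bin.
* Ties everywhere (equal MST weights, equal RMSDs, equal sort keys) break
  lexicographically, so outputs are stable across runs and platforms.
* Assembly operator expressions support identifier lists and ranges;
  parenthesised operator *compositions* (e.g. viral capsid matrix
  products) are rejected with a clear error rather than half-supported.
* When several assemblies are declared, assembly `"1"` is indexed by
  default with a CLI override — archives rarely make the choice for you,
  and the first assembly is the depositor-designated biological unit in
  the overwhelming majority of entries.

# Validation scale

The shipped suite and `scripts/acceptance.R` run entirely from synthetic
corpora sized to keep a full run in a few minutes on one core: 8–20
randomized corpora of 10–30 structures × 30–100 residues for the
oracle-equivalence property (tolerances 0–2), 10–12 structures with 6–8
planted instances per noise level for recall, 100 random pairings for the
superposition cross-check. These sizes are the package's validation
conditions; the method itself has no corpus-size limit beyond disk space,
and index growth is linear in the number of indexed pairs.

# Known limitations

* Legacy PDB input has no label-level numbering; author identifiers double
  as labels and no assembly expansion is available in that path.
* No handling of crystallographic symmetry beyond the assembly operators
  listed in the file; no occupancy/B-factor modelling; no sequence
  alignment.
* Exchange scoring by name intersection ignores atom-name symmetry, so
  chemically equivalent but differently labelled atoms do not pair.
* Recall under noise is bounded by the bin widths: strong coordinate noise
  (σ ≈ 0.3 Å) moves angle descriptors across more than one 20° bin for a
  noticeable fraction of planted instances at tolerance 1; raising the
  tolerance recovers them at the cost of more bin reads.
* No hit significance model (see above).
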
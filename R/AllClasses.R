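#' @import methods
NULL

#' PolymerStructure: an assembly-expanded polymer model
#'
#' Holds the polymer residues of one structure after parsing, biological
#' assembly expansion and stripping (hydrogens, alternate locations beyond
#' the first, waters/ions/ligands). Each residue is addressed by its
#' locator, the triple (label_asym_id, assembly operator id, label_seq_id),
#' rendered e.g. "A_1-87", and carries a backbone and a sidechain
#' representative point (C-alpha/C-beta for amino acids, C4'/C1' for
#' nucleotides; glycine's C-beta is reconstructed).
#'
#' @slot structureId Entry identifier (e.g. a 4-character PDB id or a
#'   fixture name).
#' @slot assemblyId Identifier of the expanded assembly ("asym" for the
#'   asymmetric unit).
#' @slot residues data.frame with one row per residue: chain, operator,
#'   seq, code, kind, authChain, authSeq, and representative coordinates
#'   bx, by, bz (backbone) and sx, sy, sz (sidechain).
#' @slot atoms data.frame of heavy atoms: res (row index into residues),
#'   name, x, y, z.
#' @slot report list of per-load counters (residues excluded for missing
#'   representative atoms, unmapped components, skipped pairs, ...).
#' @export
setClass("PolymerStructure",
  representation(structureId = "character",
                 assemblyId = "character",
                 residues = "data.frame",
                 atoms = "data.frame",
                 report = "list"))

setValidity("PolymerStructure", function(object) {
  res <- object@residues
  need <- c("chain", "operator", "seq", "code", "kind",
            "bx", "by", "bz", "sx", "sy", "sz")
  if (!all(need %in% names(res)))
    return(paste("residues table lacks columns:",
                 paste(setdiff(need, names(res)), collapse = ", ")))
  if (nrow(res)) {
    key <- paste(res$chain, res$operator, res$seq)
    if (anyDuplicated(key)) return("residue locators are not unique")
    if (any(res$seq < 1L)) return("label_seq_id must be >= 1")
    if (!all(is.finite(as.matrix(res[, c("bx", "by", "bz", "sx", "sy", "sz")]))))
      return("representative points must be finite")
  }
  TRUE
})

#' MotifQuery: a motif definition derived from a reference structure
#'
#' An ordered set of residue roles (each with one or more allowed residue
#' tokens -- position-specific exchanges) plus the admissible residue-pair
#' geometries measured in the reference structure (pairs with backbone
#' distance >= 20 A are inadmissible).
#'
#' @slot referenceId Identifier of the reference structure.
#' @slot residues data.frame: role, chain, operator, seq, code (one row per
#'   role, in query order).
#' @slot allowed list of character vectors, per role: allowed residue tokens
#'   (the residue's own token plus any exchanges).
#' @slot refResidues list of residue records (code, kind, atoms, backbone,
#'   sidechain) holding the reference coordinates used for scoring.
#' @slot pairs data.frame of admissible role pairs: a, b, db, ds, theta.
#' @export
setClass("MotifQuery",
  representation(referenceId = "character",
                 residues = "data.frame",
                 allowed = "list",
                 refResidues = "list",
                 pairs = "data.frame"))

setValidity("MotifQuery", function(object) {
  n <- nrow(object@residues)
  if (n < 2L) return("a motif query needs at least 2 residues")
  if (length(object@allowed) != n) return("one allowed-token set per role required")
  if (any(vapply(object@allowed, length, 1L) < 1L))
    return("every role needs at least one allowed token")
  if (nrow(object@pairs)) {
    if (any(object@pairs$a >= object@pairs$b)) return("pair roles must satisfy a < b")
    if (any(object@pairs$a < 1L | object@pairs$b > n)) return("pair role out of range")
  }
  TRUE
})

#' MotifIndex: handle to an on-disk inverted index
#'
#' A directory holding one file per descriptor bin (postings: structure id
#' -> sorted residue-pair occurrences), a residue-addressable coordinate
#' store, and a JSON manifest.
#'
#' @slot path Index directory.
#' @slot manifest Parsed manifest (schema version, indexed ids with load
#'   timestamps, total pair count, bin count).
#' @export
setClass("MotifIndex",
  representation(path = "character", manifest = "list"))

setValidity("MotifIndex", function(object) {
  if (length(object@path) != 1L) return("path must be a single directory")
  m <- object@manifest
  need <- c("schema_version", "indexed", "total_pairs", "bin_count")
  if (!all(need %in% names(m)))
    return(paste("manifest lacks fields:",
                 paste(setdiff(need, names(m)), collapse = ", ")))
  TRUE
})
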
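# Residue chemistry tables: residue-type tokens, component-id mappings, and
# standard heavy-atom name sets.
#
# Tokens: amino acids are upper-case one-letter codes; standard nucleotides
# are lower-case (a, c, g, t, u) so alanine "A" never collides with
# adenosine "a". The alphabet order below is the canonical sort order used
# for type-pair normalisation and integer packing.

#' @keywords internal
.AA_TOKENS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @keywords internal
.NT_TOKENS <- c("a", "c", "g", "t", "u")

#' Residue-type token alphabet
#'
#' The 25 residue-type tokens known to the descriptor machinery: 20 upper-case
#' amino-acid one-letter codes followed by 5 lower-case nucleotide tokens.
#' Their position in this vector defines the lexicographic order used when
#' normalising a type pair (an Ala/Cys pair is always "AC", never "CA").
#'
#' @return Character vector of length 25.
#' @export
#' @examples
#' tokenAlphabet()
tokenAlphabet <- function() c(.AA_TOKENS, .NT_TOKENS)

# three-letter component id -> one-letter token, standard amino acids
.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# standard nucleotide component ids (RNA and DNA) -> lower-case token
.NT2TOKEN <- c(
  A = "a", C = "c", G = "g", U = "u", T = "t",
  DA = "a", DC = "c", DG = "g", DT = "t", DU = "u")

#' Default mapping of modified components to parent tokens
#'
#' Post-translationally modified or otherwise non-standard polymer components
#' are translated to their parent residue token so that, e.g., a
#' phosphoserine participates in descriptors as a serine. Components absent
#' from this table (and from the standard tables) are excluded from indexing
#' and counted in the load report.
#'
#' @return Named character vector: component id -> token.
#' @export
defaultModifiedMap <- function() {
  c(MSE = "M", SEP = "S", TPO = "T", PTR = "Y", CSO = "C",
    HYP = "P", MLY = "K", PCA = "Q", KCX = "K", CME = "C",
    PSU = "u", `1MA` = "a", `5MC` = "c", `7MG` = "g")
}

#' @keywords internal
.token1to3 <- function(tok) {
  aa <- names(.AA3TO1)[match(tok, .AA3TO1)]
  nt <- c(a = "A", c = "C", g = "G", t = "DT", u = "U")[tok]
  ifelse(!is.na(aa), aa, unname(nt))
}

#' @keywords internal
.compToToken <- function(comp, modified = defaultModifiedMap()) {
  tok <- unname(.AA3TO1[comp])
  miss <- is.na(tok)
  tok[miss] <- unname(.NT2TOKEN[comp[miss]])
  miss <- is.na(tok)
  if (any(miss) && length(modified))
    tok[miss] <- unname(modified[comp[miss]])
  tok
}

#' @keywords internal
.polymerKind <- function(token) {
  ifelse(token %in% .NT_TOKENS, "nucleotide", "amino-acid")
}

# amino-acid backbone heavy-atom names; everything else is sidechain
.AA_BACKBONE <- c("N", "CA", "C", "O", "OXT")
# nucleotide sugar-phosphate "backbone"; base atoms are the sidechain
.NT_BACKBONE <- c("P", "OP1", "OP2", "OP3", "O5'", "C5'", "C4'", "O4'",
                  "C3'", "O3'", "C2'", "O2'", "C1'")

# sidechain heavy-atom names beyond CB, per amino-acid token
.AA_SIDECHAIN_EXT <- list(
  A = character(0),
  C = c("SG"),
  D = c("CG", "OD1", "OD2"),
  E = c("CG", "CD", "OE1", "OE2"),
  F = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  G = character(0),
  H = c("CG", "ND1", "CD2", "CE1", "NE2"),
  I = c("CG1", "CG2", "CD1"),
  K = c("CG", "CD", "CE", "NZ"),
  L = c("CG", "CD1", "CD2"),
  M = c("CG", "SD", "CE"),
  N = c("CG", "OD1", "ND2"),
  P = c("CG", "CD"),
  Q = c("CG", "CD", "OE1", "NE2"),
  R = c("CG", "CD", "NE", "CZ", "NH1", "NH2"),
  S = c("OG"),
  T = c("OG1", "CG2"),
  V = c("CG1", "CG2"),
  W = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  Y = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"))

# base heavy-atom names per nucleotide token
.NT_BASE <- list(
  a = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
  g = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
  c = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  u = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6"),
  t = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6"))

#' Standard heavy-atom names for a residue token
#'
#' @param token A residue-type token from \code{tokenAlphabet()}.
#' @return Character vector of heavy-atom names in conventional order.
#' @export
#' @examples
#' standardAtomNames("K")  # lysine
standardAtomNames <- function(token) {
  stopifnot(length(token) == 1L)
  if (token %in% .AA_TOKENS) {
    base <- c("N", "CA", "C", "O")
    side <- if (token == "G") character(0) else c("CB", .AA_SIDECHAIN_EXT[[token]])
    c(base, side)
  } else if (token %in% .NT_TOKENS) {
    sugar <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
               "C3'", "O3'", "C2'", "C1'")
    if (token %in% c("a", "c", "g", "u")) sugar <- append(sugar, "O2'", after = 10L)
    c(sugar, .NT_BASE[[token]])
  } else {
    stop("unknown residue token: ", token)
  }
}

#' @keywords internal
.isBackboneAtom <- function(names, kind) {
  bb <- if (identical(kind, "nucleotide")) .NT_BACKBONE else .AA_BACKBONE
  names %in% bb
}

#' @keywords internal
.elementOf <- function(atomNames) {
  # element symbol from a heavy-atom name: leading letter (S for SG/SD, P for P)
  substr(atomNames, 1L, 1L)
}
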
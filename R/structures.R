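# Structure loading: parse mmCIF (or legacy PDB via bio3d), strip
# hydrogens / alternate locations / non-polymer groups, expand the
# requested biological assembly, and populate backbone and sidechain
# representative points per residue.

#' Render residue locators
#'
#' A residue is addressed by chain (label_asym_id), assembly operator id
#' and sequence position (label_seq_id), rendered as
#' "<chain>_<operator>-<seq>", e.g. "A_1-87" for chain A under the first
#' assembly generation operation, position 87.
#'
#' @param chain,operator Character vectors.
#' @param seq Integer vector.
#' @return Character vector of rendered locators.
#' @export
#' @examples
#' renderLocator("A", "1", 87)
renderLocator <- function(chain, operator, seq) {
  sprintf("%s_%s-%d", chain, operator, as.integer(seq))
}

# total order on locators: chain, operator (C-locale strings), seq numeric
#' @keywords internal
.locatorOrder <- function(chain, operator, seq) {
  order(chain, operator, as.integer(seq), method = "radix")
}

#' @keywords internal
.locatorLess <- function(c1, o1, s1, c2, o2, s2) {
  ifelse(c1 != c2, c1 < c2, ifelse(o1 != o2, o1 < o2, s1 < s2))
}

# ---------------------------------------------------------------------------
# representative points

#' @keywords internal
.computeReps <- function(residues, atoms) {
  n <- nrow(residues)
  bx <- by <- bz <- sx <- sy <- sz <- rep(NA_real_, n)
  excluded <- character(0)
  atomsByRes <- split(seq_len(nrow(atoms)), factor(atoms$res, levels = seq_len(n)))
  for (i in seq_len(n)) {
    idx <- atomsByRes[[i]]
    nm <- atoms$name[idx]
    co <- cbind(atoms$x[idx], atoms$y[idx], atoms$z[idx])
    if (residues$kind[i] == "nucleotide") {
      b <- match("C4'", nm); s <- match("C1'", nm)
      if (is.na(b) || is.na(s)) { excluded <- c(excluded, i); next }
      bx[i] <- co[b, 1L]; by[i] <- co[b, 2L]; bz[i] <- co[b, 3L]
      sx[i] <- co[s, 1L]; sy[i] <- co[s, 2L]; sz[i] <- co[s, 3L]
    } else {
      ca <- match("CA", nm)
      if (is.na(ca)) { excluded <- c(excluded, i); next }
      cb <- match("CB", nm)
      if (is.na(cb)) {
        nn <- match("N", nm); cc <- match("C", nm)
        if (is.na(nn) || is.na(cc)) { excluded <- c(excluded, i); next }
        p <- tryCatch(reconstructGlyCb(co[nn, ], co[ca, ], co[cc, ]),
                      error = function(e) NULL)
        if (is.null(p)) { excluded <- c(excluded, i); next }
        sx[i] <- p[1L]; sy[i] <- p[2L]; sz[i] <- p[3L]
      } else {
        sx[i] <- co[cb, 1L]; sy[i] <- co[cb, 2L]; sz[i] <- co[cb, 3L]
      }
      bx[i] <- co[ca, 1L]; by[i] <- co[ca, 2L]; bz[i] <- co[ca, 3L]
    }
  }
  residues$bx <- bx; residues$by <- by; residues$bz <- bz
  residues$sx <- sx; residues$sy <- sy; residues$sz <- sz
  list(residues = residues, excluded = as.integer(excluded))
}

#' @keywords internal
.newPolymerStructure <- function(structureId, residues, atoms,
                                 assemblyId = "asym", report = list()) {
  fit <- .computeReps(residues, atoms)
  residues <- fit$residues
  if (length(fit$excluded)) {
    report$missing_representative <- length(fit$excluded)
    report$excluded_locators <- renderLocator(
      residues$chain[fit$excluded], residues$operator[fit$excluded],
      residues$seq[fit$excluded])
    keepRes <- setdiff(seq_len(nrow(residues)), fit$excluded)
    remap <- integer(nrow(residues)); remap[keepRes] <- seq_along(keepRes)
    residues <- residues[keepRes, , drop = FALSE]
    keepAtm <- atoms$res %in% keepRes
    atoms <- atoms[keepAtm, , drop = FALSE]
    atoms$res <- remap[atoms$res]
  }
  ord <- .locatorOrder(residues$chain, residues$operator, residues$seq)
  remap <- integer(nrow(residues)); remap[ord] <- seq_along(ord)
  residues <- residues[ord, , drop = FALSE]
  atoms$res <- remap[atoms$res]
  atoms <- atoms[order(atoms$res, method = "radix"), , drop = FALSE]
  rownames(residues) <- NULL
  rownames(atoms) <- NULL
  new("PolymerStructure", structureId = structureId, assemblyId = assemblyId,
      residues = residues, atoms = atoms, report = report)
}

# ---------------------------------------------------------------------------
# assembly operators

#' @keywords internal
.parseOperExpression <- function(expr) {
  if (grepl("[()]", expr)) {
    inner <- regmatches(expr, gregexpr("\\(([^)]*)\\)", expr))[[1L]]
    if (length(inner) > 1L)
      stop("operator composition expressions are not supported: ", expr)
    expr <- gsub("[()]", "", expr)
  }
  parts <- strsplit(expr, ",", fixed = TRUE)[[1L]]
  out <- character(0)
  for (p in parts) {
    if (grepl("^[0-9]+-[0-9]+$", p)) {
      rng <- as.integer(strsplit(p, "-", fixed = TRUE)[[1L]])
      out <- c(out, as.character(seq(rng[1L], rng[2L])))
    } else out <- c(out, p)
  }
  out
}

#' @keywords internal
.readOperList <- function(cats) {
  ol <- cats$pdbx_struct_oper_list
  if (is.null(ol)) return(list())
  ops <- list()
  mcols <- paste0("matrix[", rep(1:3, each = 3L), "][", rep(1:3, 3L), "]")
  vcols <- paste0("vector[", 1:3, "]")
  for (i in seq_len(nrow(ol))) {
    R <- matrix(as.numeric(unlist(ol[i, mcols])), 3L, 3L, byrow = TRUE)
    t <- as.numeric(unlist(ol[i, vcols]))
    ops[[ol$id[i]]] <- list(rotation = R, translation = t)
  }
  ops
}

#' List the biological assemblies declared in an mmCIF file
#'
#' @param source Path to an mmCIF file.
#' @return data.frame with columns assembly, operators, chains (one row per
#'   generation rule); zero rows when the file declares no assemblies.
#' @export
listAssemblies <- function(source) {
  cats <- readMmcif(source)
  ag <- cats$pdbx_struct_assembly_gen
  if (is.null(ag))
    return(data.frame(assembly = character(0), operators = character(0),
                      chains = character(0)))
  data.frame(assembly = ag$assembly_id, operators = ag$oper_expression,
             chains = ag$asym_id_list, stringsAsFactors = FALSE)
}

#' @keywords internal
.expandAssembly <- function(residues, atoms, cats, assembly) {
  identityOp <- list(rotation = diag(3), translation = c(0, 0, 0))
  ag <- cats$pdbx_struct_assembly_gen
  if (identical(assembly, "asym") || is.null(ag)) {
    residues$operator <- "1"
    return(list(residues = residues, atoms = atoms))
  }
  rows <- which(ag$assembly_id == assembly)
  if (!length(rows))
    stop("unknown assembly \"", assembly, "\"; available: ",
         paste(unique(ag$assembly_id), collapse = ", "))
  ops <- .readOperList(cats)
  outRes <- list(); outAtm <- list(); copy <- 0L
  for (r in rows) {
    operIds <- .parseOperExpression(ag$oper_expression[r])
    chains <- trimws(strsplit(ag$asym_id_list[r], ",", fixed = TRUE)[[1L]])
    selRes <- which(residues$chain %in% chains)
    if (!length(selRes)) next
    remap <- integer(nrow(residues)); remap[selRes] <- seq_along(selRes)
    selAtm <- atoms[atoms$res %in% selRes, , drop = FALSE]
    for (oid in operIds) {
      op <- ops[[oid]]
      if (is.null(op)) {
        if (oid == "1") op <- identityOp
        else stop("assembly operator \"", oid, "\" not found in oper_list")
      }
      copy <- copy + 1L
      res2 <- residues[selRes, , drop = FALSE]
      res2$operator <- oid
      atm2 <- selAtm
      xyz <- .applyRigid(cbind(atm2$x, atm2$y, atm2$z), op$rotation,
                         op$translation)
      atm2$x <- xyz[, 1L]; atm2$y <- xyz[, 2L]; atm2$z <- xyz[, 3L]
      atm2$res <- remap[atm2$res]  # re-based across copies below
      res2$.copy <- copy
      atm2$.copy <- copy
      outRes[[copy]] <- res2
      outAtm[[copy]] <- atm2
    }
  }
  if (!copy) stop("assembly \"", assembly, "\" selects no polymer chains")
  resAll <- do.call(rbind, outRes)
  offsets <- c(0L, cumsum(vapply(outRes, nrow, 1L)))
  atmAll <- do.call(rbind, lapply(seq_len(copy), function(k) {
    a <- outAtm[[k]]; a$res <- a$res + offsets[k]; a
  }))
  resAll$.copy <- NULL; atmAll$.copy <- NULL
  list(residues = resAll, atoms = atmAll)
}

# ---------------------------------------------------------------------------
# loading

#' Load a macromolecular structure
#'
#' Parses an mmCIF (or legacy PDB) file into a
#' \linkS4class{PolymerStructure}: hydrogens are removed, only the
#' first-listed alternate location of each atom is retained, non-polymer
#' groups (waters, ions, ligands) are dropped, the requested biological
#' assembly is expanded, and backbone/sidechain representative points are
#' populated (glycine's C-beta is reconstructed from a prototypic
#' L-alanine). Residues missing their representative atoms are excluded and
#' counted in the load report.
#'
#' @param source File path (mmCIF optionally gzipped).
#' @param format "mmcif" or "pdb". The legacy PDB reader (via
#'   \pkg{bio3d}) has no label-level numbering; author chain/seq ids double
#'   as label ids and no assembly expansion is available.
#' @param assembly Assembly id to expand ("1" by default); "asym" requests
#'   the asymmetric unit.
#' @param structureId Entry identifier; defaults to the file base name.
#' @param modified Named map from modified component ids to parent tokens
#'   (see \code{\link{defaultModifiedMap}}); unmapped components are
#'   excluded and counted.
#' @return A \linkS4class{PolymerStructure}.
#' @export
loadStructure <- function(source, format = c("mmcif", "pdb"), assembly = "1",
                          structureId = NULL,
                          modified = defaultModifiedMap()) {
  format <- match.arg(format)
  if (is.null(structureId))
    structureId <- sub("\\.(cif|pdb|ent)(\\.gz)?$", "",
                       basename(source), ignore.case = TRUE)
  if (format == "pdb") {
    return(.loadPdbLegacy(source, structureId, modified))
  }
  cats <- readMmcif(source)
  as <- cats$atom_site
  if (is.null(as)) stop("parse error: no atom_site category in ", source)
  need <- c("label_atom_id", "label_comp_id", "label_asym_id",
            "label_seq_id", "Cartn_x", "Cartn_y", "Cartn_z")
  if (!all(need %in% names(as)))
    stop("parse error: atom_site lacks items: ",
         paste(setdiff(need, names(as)), collapse = ", "))
  report <- list()

  if ("pdbx_PDB_model_num" %in% names(as)) {
    first <- as$pdbx_PDB_model_num[1L]
    as <- as[as$pdbx_PDB_model_num == first, , drop = FALSE]
  }
  # polymer residues carry a label_seq_id; waters/ions/ligands do not
  as <- as[!(as$label_seq_id %in% c(".", "?")), , drop = FALSE]
  # hydrogens out
  elem <- if ("type_symbol" %in% names(as)) toupper(as$type_symbol)
          else .elementOf(toupper(as$label_atom_id))
  as <- as[!(elem %in% c("H", "D")), , drop = FALSE]
  # first alternate location per atom
  if ("label_alt_id" %in% names(as)) {
    key <- paste(as$label_asym_id, as$label_seq_id, as$label_atom_id)
    dup <- duplicated(key)
    report$altloc_dropped <- sum(dup)
    as <- as[!dup, , drop = FALSE]
  }
  tok <- .compToToken(as$label_comp_id, modified)
  if (any(is.na(tok))) {
    bad <- unique(as$label_comp_id[is.na(tok)])
    report$unmapped_components <- bad
    as <- as[!is.na(tok), , drop = FALSE]
    tok <- tok[!is.na(tok)]
  }
  if (!nrow(as)) stop("empty structure: no polymer residues in ", source)

  resKey <- paste(as$label_asym_id, as$label_seq_id)
  firstIdx <- which(!duplicated(resKey))
  residues <- data.frame(
    chain = as$label_asym_id[firstIdx],
    seq = as.integer(as$label_seq_id[firstIdx]),
    code = tok[firstIdx],
    kind = .polymerKind(tok[firstIdx]),
    authChain = if ("auth_asym_id" %in% names(as)) as$auth_asym_id[firstIdx]
                else as$label_asym_id[firstIdx],
    authSeq = if ("auth_seq_id" %in% names(as))
                suppressWarnings(as.integer(as$auth_seq_id[firstIdx]))
              else as.integer(as$label_seq_id[firstIdx]),
    stringsAsFactors = FALSE)
  atoms <- data.frame(
    res = match(resKey, resKey[firstIdx]),
    name = as$label_atom_id,
    x = as.numeric(as$Cartn_x), y = as.numeric(as$Cartn_y),
    z = as.numeric(as$Cartn_z), stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x + atoms$y + atoms$z)))
    stop("parse error: non-numeric Cartn coordinates in ", source)

  ex <- .expandAssembly(residues, atoms, cats, assembly)
  .newPolymerStructure(structureId, ex$residues, ex$atoms,
                       assemblyId = assembly, report = report)
}

#' @keywords internal
.loadPdbLegacy <- function(source, structureId, modified) {
  pdb <- bio3d::read.pdb(source, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  a <- a[!(toupper(substr(a$elesy, 1L, 1L)) %in% c("H", "D")) &
           !grepl("^[0-9]*H", a$elety), , drop = FALSE]
  key <- paste(a$chain, a$resno, a$elety)
  a <- a[!duplicated(key), , drop = FALSE]
  tok <- .compToToken(a$resid, modified)
  a <- a[!is.na(tok), , drop = FALSE]
  tok <- tok[!is.na(tok)]
  if (!nrow(a)) stop("empty structure: no polymer residues in ", source)
  resKey <- paste(a$chain, a$resno)
  firstIdx <- which(!duplicated(resKey))
  residues <- data.frame(
    chain = a$chain[firstIdx], seq = as.integer(a$resno[firstIdx]),
    code = tok[firstIdx], kind = .polymerKind(tok[firstIdx]),
    authChain = a$chain[firstIdx], authSeq = as.integer(a$resno[firstIdx]),
    operator = "1", stringsAsFactors = FALSE)
  atoms <- data.frame(res = match(resKey, resKey[firstIdx]), name = a$elety,
                      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  .newPolymerStructure(structureId, residues, atoms, assemblyId = "asym")
}

#' Expand a biological assembly
#'
#' Convenience wrapper around \code{\link{loadStructure}} that loads a file
#' and expands the named assembly; each generated chain copy carries its
#' assembly operator id in the residue locator (identity renders "1").
#'
#' @param source mmCIF file path.
#' @param assembly Assembly id, or "asym" for the asymmetric unit.
#' @param ... Passed to \code{\link{loadStructure}}.
#' @return A \linkS4class{PolymerStructure}.
#' @export
expandAssembly <- function(source, assembly, ...) {
  loadStructure(source, format = "mmcif", assembly = assembly, ...)
}

# residue record used by scoring and the coordinate store: a plain list
#' @keywords internal
.residueRecord <- function(structure, i) {
  res <- structure@residues
  idx <- which(structure@atoms$res == i)
  atm <- structure@atoms[idx, , drop = FALSE]
  co <- cbind(x = atm$x, y = atm$y, z = atm$z)
  rownames(co) <- atm$name
  list(code = res$code[i], kind = res$kind[i],
       chain = res$chain[i], operator = res$operator[i], seq = res$seq[i],
       atoms = co,
       backbone = c(res$bx[i], res$by[i], res$bz[i]),
       sidechain = c(res$sx[i], res$sy[i], res$sz[i]))
}
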
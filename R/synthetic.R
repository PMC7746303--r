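# Synthetic structures and corpora with planted motif instances.
#
# The generator emulates polymer chains at the level the descriptor
# machinery cares about: C-alpha positions on a self-avoiding random walk
# with the canonical 3.8 A virtual bond, per-residue backbone atoms from a
# randomly oriented ideal-alanine fragment (so glycine C-beta
# reconstruction is exercised consistently), and deterministic sidechain
# atoms extending along the C-alpha -> C-beta direction. No Ramachandran
# statistics or sterics beyond the self-avoidance are modelled. Corpora
# are written as genuine mmCIF so tests exercise the parser, not a bypass.

#' @keywords internal
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# rotation taking unit vector a onto unit vector b (Rodrigues)
#' @keywords internal
.rotationBetween <- function(a, b) {
  a <- .unit(a); b <- .unit(b)
  v <- .cross3(a, b)
  cth <- sum(a * b)
  if (.vnorm(v) < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any perpendicular axis
    p <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- .unit(.cross3(a, p))
    v <- axis; cth <- -1
    K <- matrix(c(0, -v[3L], v[2L], v[3L], 0, -v[1L], -v[2L], v[1L], 0),
                3L, 3L, byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, -v[3L], v[2L], v[3L], 0, -v[1L], -v[2L], v[1L], 0),
              3L, 3L, byrow = TRUE)
  diag(3) + K + K %*% K * (1 / (1 + cth))
}

# one synthetic residue: ideal-alanine backbone oriented so that its
# C-beta points along cbDir, plus schematic sidechain atoms marching along
# that direction with alternating perpendicular offsets
#' @keywords internal
.syntheticResidue <- function(code, ca, cbDir, chain = "A", operator = "1",
                              seq = 1L) {
  tmpl <- .idealAlanine
  cbDir <- .unit(cbDir)
  R <- .rotationBetween(.unit(tmpl["CB", ]), cbDir)
  names <- c("N", "CA", "C", "O", if (code != "G") "CB")
  co <- .applyRigid(tmpl[names, , drop = FALSE], R, ca)
  ext <- .AA_SIDECHAIN_EXT[[code]]
  if (length(ext)) {
    perp <- .unit(.cross3(cbDir, if (abs(cbDir[1L]) < 0.9) c(1, 0, 0)
                                 else c(0, 1, 0)))
    cb <- co["CB", ]
    extCo <- t(vapply(seq_along(ext), function(k) {
      cb + 1.45 * k * cbDir + 0.45 * (-1)^k * perp
    }, numeric(3L)))
    rownames(extCo) <- ext
    co <- rbind(co, extCo)
  }
  bb <- co["CA", ]
  sc <- if (code == "G") as.vector(R %*% tmpl["CB", ] + ca) else co["CB", ]
  list(code = code, kind = "amino-acid", chain = chain, operator = operator,
       seq = as.integer(seq), atoms = co, backbone = bb, sidechain = sc)
}

#' @keywords internal
.generateStructureCore <- function(nResidues, structureId, chain = "A") {
  stopifnot(nResidues >= 1L)
  ca <- matrix(0, nResidues, 3L)
  for (i in seq_len(nResidues)[-1L]) {
    for (try in seq_len(1000L)) {
      d <- stats::rnorm(3L)
      p <- ca[i - 1L, ] + 3.8 * d / .vnorm(d)
      if (i == 2L || min(sqrt(rowSums(sweep(ca[seq_len(i - 2L), , drop = FALSE],
                                            2L, p)^2))) >= 3.4) break
      p <- NULL
    }
    if (is.null(p)) stop("self-avoiding walk failed; chain too dense")
    ca[i, ] <- p
  }
  codes <- sample(.AA_TOKENS, nResidues, replace = TRUE)
  recs <- lapply(seq_len(nResidues), function(i) {
    d <- stats::rnorm(3L)
    .syntheticResidue(codes[i], ca[i, ], d / .vnorm(d), chain = chain,
                      seq = i)
  })
  .structureFromRecords(structureId, recs)
}

#' @keywords internal
.structureFromRecords <- function(structureId, recs, assemblyId = "asym") {
  residues <- data.frame(
    chain = vapply(recs, `[[`, "", "chain"),
    operator = vapply(recs, function(r) r$operator %||% "1", ""),
    seq = vapply(recs, `[[`, 1L, "seq"),
    code = vapply(recs, `[[`, "", "code"),
    kind = vapply(recs, `[[`, "", "kind"),
    stringsAsFactors = FALSE)
  residues$authChain <- residues$chain
  residues$authSeq <- residues$seq
  atoms <- do.call(rbind, lapply(seq_along(recs), function(i) {
    co <- recs[[i]]$atoms
    data.frame(res = i, name = rownames(co), x = co[, 1L], y = co[, 2L],
               z = co[, 3L], stringsAsFactors = FALSE)
  }))
  .newPolymerStructure(structureId, residues, atoms, assemblyId = assemblyId)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic polymer structure
#'
#' Deterministic given the seed: consecutive backbone representatives sit
#' exactly 3.8 A apart on a self-avoiding random walk, each sidechain
#' representative points 1.53 A from its C-alpha in a random direction
#' (the ideal-alanine C-alpha/C-beta distance), residue types are drawn
#' uniformly from the 20 amino acids, and full backbone/sidechain atom
#' sets are synthesised consistently with the representatives.
#'
#' @param nResidues Number of residues (>= 1).
#' @param seed Integer seed.
#' @param structureId Entry identifier (default "SYN").
#' @return A \linkS4class{PolymerStructure} (single chain "A", asymmetric
#'   unit).
#' @export
generateStructure <- function(nResidues, seed, structureId = "SYN") {
  .withSeed(seed, .generateStructureCore(nResidues, structureId))
}

#' A synthetic catalytic-triad-like motif
#'
#' Three residues (His, Asp, Ser) in a serine-protease-like arrangement:
#' the His/Ser pair has backbone distance 8.45 A, sidechain distance
#' ~7.6 A and inter-vector angle 105 degrees, i.e. the canonical geometry
#' range of the catalytic triad of chymotrypsin-family proteases. The
#' coordinates are synthetic (constructed from ideal fragments, not taken
#' from any PDB entry) and serve as the packaged stand-in for a real triad
#' in examples and validation.
#'
#' @return List of three residue records (roles: His, Asp, Ser).
#' @export
syntheticTriadMotif <- function() {
  deg <- pi / 180
  list(
    .syntheticResidue("H", c(0, 0, 0), c(cos(100 * deg), sin(100 * deg), 0),
                      seq = 1L),
    .syntheticResidue("D", c(4.2, 5.0, 0), c(0, 0.809, 0.588), seq = 2L),
    .syntheticResidue("S", c(8.45, 0, 0), c(cos(205 * deg), sin(205 * deg), 0),
                      seq = 3L))
}

#' Materialise a motif as a reference structure
#'
#' Wraps a list of residue records (e.g. \code{\link{syntheticTriadMotif}})
#' as a \linkS4class{PolymerStructure} with chain "A" and sequence
#' positions 1..n, usable as the reference of \code{\link{defineQuery}}.
#'
#' @param motif List of residue records.
#' @param structureId Identifier for the wrapper structure.
#' @return A \linkS4class{PolymerStructure}.
#' @export
motifAsStructure <- function(motif, structureId = "QUERY") {
  recs <- lapply(seq_along(motif), function(i) {
    r <- motif[[i]]; r$chain <- "A"; r$operator <- "1"; r$seq <- i; r
  })
  .structureFromRecords(structureId, recs)
}

#' Plant a motif instance into a structure
#'
#' Applies a rigid transform to the motif coordinates, perturbs every atom
#' coordinate with independent Gaussian noise of standard deviation
#' \code{sigma}, and substitutes the result at the insertion locators
#' (replacing those residues' identities and atoms). The returned truth
#' row records the ground-truth role assignment.
#'
#' @param structure A \linkS4class{PolymerStructure}.
#' @param motif List of residue records.
#' @param at Insertion locators: integer sequence positions in chain "A"
#'   (or a data.frame with chain, operator, seq), one per role, distinct.
#' @param rotation,translation The rigid transform applied to the motif
#'   (defaults: identity, zero).
#' @param sigma Per-coordinate Gaussian noise in Angstrom (>= 0).
#' @param seed Optional seed for the noise.
#' @return List: \code{structure} (with the planted instance) and
#'   \code{truth} (data.frame: structure_id, role, chain, operator, seq,
#'   sigma).
#' @export
plantMotif <- function(structure, motif, at, rotation = diag(3),
                       translation = c(0, 0, 0), sigma = 0, seed = NULL) {
  stopifnot(sigma >= 0)
  if (!is.data.frame(at))
    at <- data.frame(chain = "A", operator = "1", seq = as.integer(at),
                     stringsAsFactors = FALSE)
  if (nrow(at) != length(motif))
    stop("need one insertion locator per motif role")
  if (anyDuplicated(paste(at$chain, at$operator, at$seq)))
    stop("locator collision: duplicated insertion locators")
  doPlant <- function() {
    res <- structure@residues
    atoms <- structure@atoms
    rows <- vapply(seq_len(nrow(at)), function(k) {
      hit <- which(res$chain == at$chain[k] & res$operator == at$operator[k] &
                     res$seq == at$seq[k])
      if (!length(hit))
        stop("insertion locator not present: ",
             renderLocator(at$chain[k], at$operator[k], at$seq[k]))
      hit[1L]
    }, 1L)
    for (k in seq_along(motif)) {
      i <- rows[k]
      co <- .applyRigid(motif[[k]]$atoms, rotation, translation)
      if (sigma > 0)
        co <- co + matrix(stats::rnorm(length(co), 0, sigma), nrow(co), 3L)
      res$code[i] <- motif[[k]]$code
      res$kind[i] <- motif[[k]]$kind
      atoms <- atoms[atoms$res != i, , drop = FALSE]
      atoms <- rbind(atoms, data.frame(res = i, name = rownames(co),
                                       x = co[, 1L], y = co[, 2L],
                                       z = co[, 3L], stringsAsFactors = FALSE))
    }
    planted <- .newPolymerStructure(structure@structureId, res, atoms,
                                    assemblyId = structure@assemblyId,
                                    report = structure@report)
    truth <- data.frame(structure_id = structure@structureId,
                        role = seq_along(motif), chain = at$chain,
                        operator = at$operator, seq = at$seq, sigma = sigma,
                        stringsAsFactors = FALSE)
    list(structure = planted, truth = truth)
  }
  if (is.null(seed)) doPlant() else .withSeed(seed, doPlant())
}

#' Generate a benchmark corpus with planted motif instances
#'
#' Writes \code{nStructures} synthetic structures as mmCIF into a
#' directory; the first \code{nPlanted} of them each contain one planted
#' instance of the motif under a random rigid transform and per-coordinate
#' Gaussian noise \code{sigma}. Deterministic given the seed. A truth
#' table (CSV) is written alongside.
#'
#' @param nStructures,nPlanted Corpus size and number of planted instances
#'   (\code{nPlanted <= nStructures}).
#' @param motif List of residue records (default
#'   \code{\link{syntheticTriadMotif}()}).
#' @param sigma Per-coordinate noise (Angstrom).
#' @param seed Integer seed.
#' @param dir Output directory (created; must not already contain a corpus).
#' @param nResidues Integer range (length 2) of per-structure residue
#'   counts, sampled uniformly.
#' @return List: \code{dir}, \code{files}, and \code{truth} (data.frame,
#'   one row per planted role).
#' @export
makeBenchmarkCorpus <- function(nStructures, nPlanted,
                                motif = syntheticTriadMotif(), sigma = 0,
                                seed = 1L, dir = tempfile("corpus"),
                                nResidues = c(30L, 100L)) {
  stopifnot(nPlanted <= nStructures, sigma >= 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  k <- length(motif)
  .withSeed(seed, {
    files <- character(nStructures)
    truth <- list()
    for (i in seq_len(nStructures)) {
      id <- sprintf("SYN%04d", i)
      n <- sample(seq(nResidues[1L], nResidues[2L]), 1L)
      s <- .generateStructureCore(n, id)
      if (i <= nPlanted) {
        at <- sort(sample(seq_len(n), k))
        R <- .randomRotation()
        centroid <- colMeans(as.matrix(s@residues[, c("bx", "by", "bz")]))
        t <- centroid + stats::rnorm(3L, 0, 2)
        pl <- plantMotif(s, motif, at, rotation = R, translation = t,
                         sigma = sigma)
        s <- pl$structure
        truth[[i]] <- pl$truth
      }
      files[i] <- file.path(dir, paste0(id, ".cif"))
      writeMmcif(s, files[i])
    }
    truth <- if (length(truth)) do.call(rbind, truth)
             else data.frame(structure_id = character(0), role = integer(0),
                             chain = character(0), operator = character(0),
                             seq = integer(0), sigma = numeric(0))
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    list(dir = dir, files = files, truth = truth)
  })
}
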
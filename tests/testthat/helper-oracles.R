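# Independent oracles and small fixture builders shared across the suite.
# Everything here is deliberately naive (double loops, direct formulas) and
# avoids the package's descriptor/index code paths so it can serve as an
# independent reference.

# --- plain vector helpers -------------------------------------------------

oracleNorm <- function(v) sqrt(sum(v^2))

oracleAngleDeg <- function(u, v) {
  ct <- sum(u * v) / (oracleNorm(u) * oracleNorm(v))
  acos(min(1, max(-1, ct))) * 180 / pi
}

randomRotationMatrix <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr0 <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr0)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# --- Kabsch (SVD) superposition oracle ------------------------------------

kabschRmsd <- function(x, y) {
  # optimal proper rotation mapping x onto y, by SVD
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  resid <- yc - xc %*% t(R)
  sqrt(sum(resid^2) / nrow(x))
}

# --- descriptor oracle ----------------------------------------------------

# geometry of two residue-table rows, straight from the representative points
oracleGeometry <- function(res, i, j) {
  b1 <- c(res$bx[i], res$by[i], res$bz[i]); b2 <- c(res$bx[j], res$by[j], res$bz[j])
  s1 <- c(res$sx[i], res$sy[i], res$sz[i]); s2 <- c(res$sx[j], res$sy[j], res$sz[j])
  list(db = oracleNorm(b1 - b2), ds = oracleNorm(s1 - s2),
       theta = oracleAngleDeg(s1 - b1, s2 - b2))
}

oracleBins <- function(g) {
  c(db = floor(g$db), ds = floor(g$ds), theta = min(floor(g$theta / 20), 8))
}

# indexable at all? (mirrors the documented d_b cutoff and d_s ceiling)
oracleIndexable <- function(g) g$db < 20 && floor(g$ds) <= 31

# enumerate all within-cutoff unordered pairs of a structure by double loop
oraclePairs <- function(structure, cutoff = 20) {
  res <- residueTable(structure)
  n <- nrow(res)
  out <- list()
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    g <- oracleGeometry(res, i, j)
    if (g$db >= cutoff || floor(g$ds) > 31) next
    b <- oracleBins(g)
    toks <- sort(c(res$code[i], res$code[j]), method = "radix")
    out[[length(out) + 1]] <- data.frame(
      typePair = paste(toks, collapse = ""),
      db = b[["db"]], ds = b[["ds"]], theta = b[["theta"]],
      i = i, j = j, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(typePair = character(0), db = integer(0), ds = integer(0),
                  theta = integer(0), i = integer(0), j = integer(0))
}

# --- brute-force candidate oracle ----------------------------------------
# All injective role->residue assignments of one structure whose every
# query edge geometry falls within the tolerance-expanded bins of the
# reference geometry. Ignores the inverted index entirely.

oracleCandidates <- function(structure, queryEdges, allowedTokens, tolerance) {
  res <- residueTable(structure)
  nRoles <- length(allowedTokens)
  roleMatches <- lapply(allowedTokens, function(toks) which(res$code %in% toks))
  if (any(vapply(roleMatches, length, 1L) == 0)) return(character(0))
  refBins <- lapply(seq_len(nrow(queryEdges)), function(e)
    oracleBins(list(db = queryEdges$db[e], ds = queryEdges$ds[e],
                    theta = queryEdges$theta[e])))
  edgeOk <- function(e, ri, rj) {
    g <- oracleGeometry(res, ri, rj)
    if (!oracleIndexable(g)) return(FALSE)
    all(abs(oracleBins(g) - refBins[[e]]) <= tolerance)
  }
  hits <- character(0)
  recurse <- function(role, chosen) {
    if (role > nRoles) {
      hits[[length(hits) + 1]] <<- paste(
        renderLocator(res$chain[chosen], res$operator[chosen],
                      res$seq[chosen]), collapse = ",")
      return(invisible())
    }
    for (cand in roleMatches[[role]]) {
      if (cand %in% chosen) next
      ok <- TRUE
      for (e in seq_len(nrow(queryEdges))) {
        a <- queryEdges$a[e]; b <- queryEdges$b[e]
        if (b == role && a < role) { if (!edgeOk(e, chosen[a], cand)) { ok <- FALSE; break } }
        else if (a == role && b < role) { if (!edgeOk(e, cand, chosen[b])) { ok <- FALSE; break } }
      }
      if (ok) recurse(role + 1, c(chosen, cand))
    }
  }
  recurse(1, integer(0))
  sort(hits)
}

# candidate strings from the package's assembly, same rendering as above
packageCandidates <- function(cands, sid, nRoles) {
  rows <- cands[cands$sid == sid, , drop = FALSE]
  if (!nrow(rows)) return(character(0))
  unname(sort(apply(rows[, paste0("role", seq_len(nRoles)), drop = FALSE], 1,
                    paste, collapse = ",")))
}

# --- tiny hand-written mmCIF fixture --------------------------------------

# two residues (Ala, Gly) with full-precision coordinates; enough to
# exercise parsing, stripping and glycine C-beta reconstruction
writeTwoResidueCif <- function(path) {
  tmpl <- idealAlanine()
  lines <- c(
    "data_FIX2", "#",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_comp_id", "_atom_site.pdbx_PDB_model_num")
  emit <- function(id, el, name, comp, seq, xyz, authSeq)
    sprintf("ATOM %d %s %s . %s A 1 %d %.3f %.3f %.3f 1.00 0.00 %d A %s 1",
            id, el, name, comp, seq, xyz[1], xyz[2], xyz[3], authSeq, comp)
  id <- 0
  for (a in c("N", "CA", "C", "O", "CB")) {
    id <- id + 1
    lines <- c(lines, emit(id, substr(a, 1, 1), a, "ALA", 1, tmpl[a, ], 11))
  }
  for (a in c("N", "CA", "C", "O")) {
    id <- id + 1
    lines <- c(lines, emit(id, substr(a, 1, 1), a, "GLY", 2,
                           tmpl[a, ] + c(3.8, 0, 0), 12))
  }
  # a water and a hydrogen that must both be stripped
  lines <- c(lines,
    "HETATM 99 O O . HOH B 2 . 1.0 2.0 3.0 1.00 0.00 101 A HOH 1",
    "ATOM 100 H H . ALA A 1 1 0.500 0.500 0.500 1.00 0.00 11 A ALA 1",
    "#")
  writeLines(lines, path)
  path
}

# small deterministic corpus shared by index tests
smallCorpus <- function(n = 6, planted = 2, sigma = 0, seed = 99,
                        nResidues = c(20L, 40L)) {
  makeBenchmarkCorpus(n, planted, sigma = sigma, seed = seed,
                      dir = tempfile("corpus"), nResidues = nResidues)
}

# run expr under a temporary RNG seed, restoring the ambient stream
.withSeedHelper <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

triadQuery <- function() {
  defineQuery(motifAsStructure(syntheticTriadMotif()),
              c("A-1", "A-2", "A-3"))
}
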
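# Residue-addressable coordinate store.
#
# Scoring needs the coordinates of a handful of residues from each
# candidate structure; reading whole coordinate files back in would
# dominate the runtime. The store therefore keeps, per structure, a small
# locator->offset table plus a flat binary record file, so any residue can
# be fetched by seeking to its record without touching sibling residues.
# Coordinates are persisted at 0.1 A precision (deci-Angstrom integers),
# which has a negligible effect on RMSD values while shrinking records.

.STORE_DIR <- "store"

#' @keywords internal
.storePaths <- function(storeDir, structureId) {
  list(idx = file.path(storeDir, paste0(structureId, ".idx.rds")),
       dat = file.path(storeDir, paste0(structureId, ".dat")))
}

# record layout (little-endian):
#   int32 natoms
#   int32 x6: backbone/sidechain representative, deci-Angstrom
#   per atom: uint8 name length, name bytes, int32 x3 deci-Angstrom
#' @keywords internal
.writeStoreEntry <- function(storeDir, structure) {
  p <- .storePaths(storeDir, structure@structureId)
  res <- structure@residues
  con <- file(p$dat, "wb")
  on.exit(close(con))
  offsets <- numeric(nrow(res))
  nbytes <- integer(nrow(res))
  atomsByRes <- split(seq_len(nrow(structure@atoms)),
                      factor(structure@atoms$res, levels = seq_len(nrow(res))))
  pos <- 0
  deci <- function(x) as.integer(round(x * 10))
  for (i in seq_len(nrow(res))) {
    idx <- atomsByRes[[i]]
    nm <- structure@atoms$name[idx]
    nameBytes <- lapply(nm, charToRaw)
    reps <- deci(c(res$bx[i], res$by[i], res$bz[i],
                   res$sx[i], res$sy[i], res$sz[i]))
    co <- deci(c(t(cbind(structure@atoms$x[idx], structure@atoms$y[idx],
                         structure@atoms$z[idx]))))
    offsets[i] <- pos
    writeBin(c(length(idx), reps), con, size = 4L, endian = "little")
    size <- 4L * 7L
    for (k in seq_along(idx)) {
      writeBin(as.raw(length(nameBytes[[k]])), con)
      writeBin(nameBytes[[k]], con)
      writeBin(co[(3L * k - 2L):(3L * k)], con, size = 4L, endian = "little")
      size <- size + 1L + length(nameBytes[[k]]) + 12L
    }
    nbytes[i] <- size
    pos <- pos + size
  }
  idxDf <- data.frame(chain = res$chain, operator = res$operator,
                      seq = res$seq, code = res$code, kind = res$kind,
                      offset = offsets, nbytes = nbytes,
                      stringsAsFactors = FALSE)
  saveRDS(idxDf, p$idx, compress = FALSE)
  invisible(p)
}

#' Fetch residues from the coordinate store
#'
#' Reads exactly the requested residue records (stored-precision, 0.1 A,
#' coordinates) from a structure's record file, seeking directly to each
#' record. The returned records carry the residue code, polymer kind, atom
#' coordinates and the representative points.
#'
#' @param index A \linkS4class{MotifIndex} (whose directory contains the
#'   store), or a store directory path.
#' @param structureId Structure identifier.
#' @param locators data.frame with columns chain, operator, seq (or a list
#'   of selector strings like "A_1-87").
#' @return List of residue records, in request order. Attribute
#'   "bytes_read" reports how many payload bytes were read from the record
#'   file (the per-structure offset table is always read in full).
#' @export
fetchResidues <- function(index, structureId, locators) {
  storeDir <- if (is(index, "MotifIndex")) file.path(index@path, .STORE_DIR)
              else index
  p <- .storePaths(storeDir, structureId)
  if (!file.exists(p$idx))
    stop("missing structure in coordinate store: ", structureId)
  if (!is.data.frame(locators)) {
    parsed <- lapply(locators, .parseSelector)
    locators <- data.frame(
      chain = vapply(parsed, `[[`, "", "chain"),
      operator = vapply(parsed, `[[`, "", "operator"),
      seq = vapply(parsed, `[[`, 1L, "seq"), stringsAsFactors = FALSE)
  }
  idx <- readRDS(p$idx)
  if (!nrow(locators)) return(structure(list(), bytes_read = 0))
  key <- paste(idx$chain, idx$operator, idx$seq)
  want <- paste(locators$chain, locators$operator, locators$seq)
  rows <- match(want, key)
  if (anyNA(rows))
    stop("missing residue ", renderLocator(
      locators$chain[which(is.na(rows))[1L]],
      locators$operator[which(is.na(rows))[1L]],
      locators$seq[which(is.na(rows))[1L]]), " in store entry ", structureId)
  con <- file(p$dat, "rb")
  on.exit(close(con))
  bytes <- 0
  out <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    i <- rows[k]
    seek(con, where = idx$offset[i], origin = "start")
    hdr <- readBin(con, "integer", n = 7L, size = 4L, endian = "little")
    natoms <- hdr[1L]
    reps <- hdr[-1L] / 10
    nm <- character(natoms)
    co <- matrix(0, natoms, 3L, dimnames = list(NULL, c("x", "y", "z")))
    for (a in seq_len(natoms)) {
      len <- as.integer(readBin(con, "raw", n = 1L))
      nm[a] <- rawToChar(readBin(con, "raw", n = len))
      co[a, ] <- readBin(con, "integer", n = 3L, size = 4L,
                         endian = "little") / 10
    }
    rownames(co) <- nm
    bytes <- bytes + idx$nbytes[i]
    out[[k]] <- list(code = idx$code[i], kind = idx$kind[i],
                     chain = idx$chain[i], operator = idx$operator[i],
                     seq = idx$seq[i], atoms = co,
                     backbone = reps[1:3], sidechain = reps[4:6])
  }
  attr(out, "bytes_read") <- bytes
  out
}
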
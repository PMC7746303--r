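# The word-level inverted index: descriptor bin -> structure id -> sorted
# residue-pair occurrences. One file per bin, named by the packed key under
# a two-level fan-out (type pair / packed key), with a JSON manifest and a
# residue-addressable coordinate store alongside. Builds stage into a
# temporary directory and publish by rename; the manifest carries a
# checksum over the logical content so partial writes are detectable.

.BINS_DIR <- "bins"
.MANIFEST <- "manifest.json"
.SCHEMA_VERSION <- 1L

#' @keywords internal
.binPath <- function(path, packed) {
  key <- decodeKey(packed)
  file.path(path, .BINS_DIR, key$typePair, sprintf("%d.rds", packed))
}

# canonical bin payload from parallel occurrence vectors
#' @keywords internal
.canonicalBinVec <- function(sid, chain1, operator1, seq1, chain2, operator2,
                             seq2, flag) {
  ord <- order(sid, chain1, operator1, seq1, chain2, operator2, seq2,
               method = "radix")
  sid <- sid[ord]; chain1 <- chain1[ord]; operator1 <- operator1[ord]
  seq1 <- seq1[ord]; chain2 <- chain2[ord]; operator2 <- operator2[ord]
  seq2 <- seq2[ord]; flag <- flag[ord]
  dup <- duplicated(paste(sid, chain1, operator1, seq1, chain2, operator2, seq2))
  if (any(dup)) {
    keep <- !dup
    sid <- sid[keep]; chain1 <- chain1[keep]; operator1 <- operator1[keep]
    seq1 <- seq1[keep]; chain2 <- chain2[keep]; operator2 <- operator2[keep]
    seq2 <- seq2[keep]; flag <- flag[keep]
  }
  chains <- sort(unique(c(chain1, chain2)), method = "radix")
  operators <- sort(unique(c(operator1, operator2)), method = "radix")
  sids <- unique(sid)
  m <- cbind(c1 = match(chain1, chains), o1 = match(operator1, operators),
             s1 = as.integer(seq1),
             c2 = match(chain2, chains), o2 = match(operator2, operators),
             s2 = as.integer(seq2), flag = as.integer(flag))
  occ <- lapply(split(seq_along(sid), factor(sid, levels = sids)),
                function(idx) m[idx, , drop = FALSE])
  names(occ) <- NULL
  list(v = .SCHEMA_VERSION, chains = chains, operators = operators,
       structures = sids, occ = occ)
}

#' @keywords internal
.canonicalBin <- function(df) {
  .canonicalBinVec(df$sid, df$chain1, df$operator1, df$seq1,
                   df$chain2, df$operator2, df$seq2, df$flag)
}

#' @keywords internal
.binToDf <- function(payload) {
  if (is.null(payload) || !length(payload$structures))
    return(data.frame(sid = character(0), chain1 = character(0),
                      operator1 = character(0), seq1 = integer(0),
                      chain2 = character(0), operator2 = character(0),
                      seq2 = integer(0), flag = integer(0),
                      stringsAsFactors = FALSE))
  parts <- lapply(seq_along(payload$structures), function(k) {
    m <- payload$occ[[k]]
    data.frame(sid = payload$structures[k],
               chain1 = payload$chains[m[, "c1"]],
               operator1 = payload$operators[m[, "o1"]],
               seq1 = as.integer(m[, "s1"]),
               chain2 = payload$chains[m[, "c2"]],
               operator2 = payload$operators[m[, "o2"]],
               seq2 = as.integer(m[, "s2"]),
               flag = as.integer(m[, "flag"]), stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

#' @keywords internal
.manifestChecksum <- function(manifest) {
  ids <- sort(names(manifest$indexed))
  canon <- paste(manifest$schema_version, manifest$total_pairs,
                 manifest$bin_count, paste(ids, collapse = ","), sep = "|")
  tf <- tempfile()
  writeLines(canon, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

#' @keywords internal
.writeManifest <- function(path, manifest) {
  manifest$checksum <- .manifestChecksum(manifest)
  jsonlite::write_json(manifest, file.path(path, .MANIFEST),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' @keywords internal
.readManifest <- function(path) {
  f <- file.path(path, .MANIFEST)
  if (!file.exists(f)) stop("not an index directory (no manifest): ", path)
  m <- jsonlite::read_json(f)
  m$indexed <- lapply(m$indexed, as.character)
  m$total_pairs <- as.integer(m$total_pairs)
  m$bin_count <- as.integer(m$bin_count)
  m$schema_version <- as.integer(m$schema_version)
  stored <- m$checksum
  m$checksum <- NULL
  if (!identical(unname(as.character(stored)), .manifestChecksum(m)))
    stop("integrity error: manifest checksum mismatch in ", path)
  m
}

#' @keywords internal
.resolveStructures <- function(structures, assembly = "1") {
  if (is(structures, "PolymerStructure")) return(list(structures))
  if (is.character(structures)) {
    if (length(structures) == 1L && dir.exists(structures))
      structures <- sort(list.files(structures, pattern = "\\.cif(\\.gz)?$",
                                    full.names = TRUE))
    return(lapply(structures, loadStructure, assembly = assembly))
  }
  stopifnot(is.list(structures))
  structures
}

#' Build an inverted index
#'
#' Indexes every within-cutoff residue pair of every input structure into
#' one bin file per descriptor, writes the coordinate store, and publishes
#' the index directory atomically (staged under a temporary name, then
#' renamed).
#'
#' @param structures A list of \linkS4class{PolymerStructure} objects, a
#'   character vector of mmCIF paths, or a directory containing .cif files.
#' @param destination Index directory to create (must not exist).
#' @param cutoff Backbone-distance indexing cutoff in Angstrom.
#' @param assembly Assembly expanded when loading from file paths.
#' @return A \linkS4class{MotifIndex}.
#' @export
buildIndex <- function(structures, destination, cutoff = 20, assembly = "1") {
  structures <- .resolveStructures(structures, assembly)
  ids <- vapply(structures, structureId, "")
  if (anyDuplicated(ids))
    stop("duplicate structure_id: ", ids[anyDuplicated(ids)])
  if (file.exists(destination))
    stop("destination already exists: ", destination)
  parent <- dirname(destination)
  if (!dir.exists(parent) || file.access(parent, 2L) != 0L)
    stop("destination not writable: ", destination)
  staging <- paste0(destination, ".staging-", Sys.getpid())
  dir.create(staging, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(staging, recursive = TRUE))
  dir.create(file.path(staging, .BINS_DIR))
  dir.create(file.path(staging, .STORE_DIR))

  manifest <- .indexInto(staging, structures, cutoff,
                         manifest = list(schema_version = .SCHEMA_VERSION,
                                         cutoff = cutoff,
                                         indexed = structure(list(), names = character(0)),
                                         total_pairs = 0L, bin_count = 0L))
  .writeManifest(staging, manifest)
  if (!file.rename(staging, destination))
    stop("failed to publish index at ", destination)
  ok <- TRUE
  new("MotifIndex", path = destination, manifest = manifest)
}

# core of build/update: add structures' pairs into bins under `path`
#' @keywords internal
.indexInto <- function(path, structures, cutoff, manifest) {
  pairParts <- vector("list", length(structures))
  stamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  for (k in seq_along(structures)) {
    s <- structures[[k]]
    pr <- enumeratePairs(s, cutoff = cutoff)
    if (nrow(pr)) pr$sid <- s@structureId
    pairParts[[k]] <- pr
    .writeStoreEntry(file.path(path, .STORE_DIR), s)
    manifest$indexed[[s@structureId]] <- stamp
  }
  pairParts <- pairParts[vapply(pairParts, nrow, 1L) > 0L]
  newPairs <- if (length(pairParts)) do.call(rbind, pairParts) else NULL
  if (!is.null(newPairs)) {
    ord <- order(newPairs$key, method = "radix")
    key <- newPairs$key[ord]
    sid <- newPairs$sid[ord]
    c1 <- newPairs$chain1[ord]; o1 <- newPairs$operator1[ord]
    s1 <- newPairs$seq1[ord]
    c2 <- newPairs$chain2[ord]; o2 <- newPairs$operator2[ord]
    s2 <- newPairs$seq2[ord]
    fl <- newPairs$flag[ord]
    # vectorized bin paths: type pair from the packed key
    alpha <- tokenAlphabet(); na <- length(alpha)
    p <- key %/% (.DB_BINS * .DS_BINS * .TH_BINS)
    tp <- paste0(alpha[p %/% na + 1L], alpha[p %% na + 1L])
    for (d in unique(tp))
      dir.create(file.path(path, .BINS_DIR, d), showWarnings = FALSE)
    files <- file.path(path, .BINS_DIR, tp, sprintf("%d.rds", key))
    ends <- c(which(key[-1L] != key[-length(key)]), length(key))
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    for (g in seq_along(starts)) {
      i <- starts[g]:ends[g]
      f <- files[starts[g]]
      gsid <- sid[i]; gc1 <- c1[i]; go1 <- o1[i]; gs1 <- s1[i]
      gc2 <- c2[i]; go2 <- o2[i]; gs2 <- s2[i]; gfl <- fl[i]
      nOld <- 0L
      if (file.exists(f)) {
        old <- .binToDf(readRDS(f))
        nOld <- nrow(old)
        gsid <- c(old$sid, gsid)
        gc1 <- c(old$chain1, gc1); go1 <- c(old$operator1, go1)
        gs1 <- c(old$seq1, gs1)
        gc2 <- c(old$chain2, gc2); go2 <- c(old$operator2, go2)
        gs2 <- c(old$seq2, gs2); gfl <- c(old$flag, gfl)
      } else {
        manifest$bin_count <- manifest$bin_count + 1L
      }
      payload <- .canonicalBinVec(gsid, gc1, go1, gs1, gc2, go2, gs2, gfl)
      manifest$total_pairs <- manifest$total_pairs +
        sum(vapply(payload$occ, nrow, 1L)) - nOld
      saveRDS(payload, f, compress = FALSE)
    }
  }
  manifest
}

#' @keywords internal
.listBins <- function(path) {
  list.files(file.path(path, .BINS_DIR), pattern = "^[0-9]+\\.rds$",
             recursive = TRUE, full.names = TRUE)
}

#' @keywords internal
.countOccurrences <- function(path) {
  total <- 0L
  for (f in .listBins(path)) {
    p <- readRDS(f)
    total <- total + sum(vapply(p$occ, nrow, 1L))
  }
  total
}

#' Open an existing index
#'
#' @param path Index directory created by \code{\link{buildIndex}}.
#' @return A \linkS4class{MotifIndex}.
#' @export
openIndex <- function(path) {
  new("MotifIndex", path = path, manifest = .readManifest(path))
}

#' Incrementally update an index
#'
#' Adds newly deposited structures to an existing index. The result is
#' bin-for-bin identical to a fresh build over the union corpus. Existing
#' structure ids are an error unless \code{replace = TRUE}, in which case
#' their previous occurrences are removed first.
#'
#' @param index A \linkS4class{MotifIndex}.
#' @param structures New structures (same forms as \code{\link{buildIndex}}).
#' @param replace Allow replacing already-indexed ids.
#' @param assembly Assembly expanded when loading from file paths.
#' @return The updated \linkS4class{MotifIndex}.
#' @export
updateIndex <- function(index, structures, replace = FALSE, assembly = "1") {
  stopifnot(is(index, "MotifIndex"))
  path <- index@path
  manifest <- .readManifest(path)
  structures <- .resolveStructures(structures, assembly)
  ids <- vapply(structures, structureId, "")
  if (anyDuplicated(ids)) stop("duplicate structure_id: ", ids[anyDuplicated(ids)])
  clash <- intersect(ids, names(manifest$indexed))
  if (length(clash) && !replace)
    stop("structure id(s) already indexed (use replace = TRUE): ",
         paste(clash, collapse = ", "))
  if (length(clash)) {
    for (f in .listBins(path)) {
      p <- readRDS(f)
      if (!any(clash %in% p$structures)) next
      df <- .binToDf(p)
      keep <- !(df$sid %in% clash)
      manifest$total_pairs <- manifest$total_pairs - sum(!keep)
      df <- df[keep, , drop = FALSE]
      if (nrow(df)) saveRDS(.canonicalBin(df), f, compress = FALSE)
      else { unlink(f); manifest$bin_count <- manifest$bin_count - 1L }
    }
    for (id in clash) manifest$indexed[[id]] <- NULL
  }
  manifest <- .indexInto(path, structures, manifest$cutoff, manifest)
  manifest <- .writeManifest(path, manifest)
  new("MotifIndex", path = path, manifest = manifest)
}

#' Look up a descriptor bin
#'
#' @param index A \linkS4class{MotifIndex}.
#' @param key Descriptor key: packed integer, key list, or rendered string
#'   like "HS-8-7-5".
#' @return data.frame of postings with columns sid, chain1, operator1,
#'   seq1, chain2, operator2, seq2, flag (zero rows for an absent bin).
#' @export
lookupBin <- function(index, key) {
  stopifnot(is(index, "MotifIndex"))
  if (is.character(key)) key <- parseKey(key)
  packed <- if (is.numeric(key)) as.integer(key) else key$packed
  f <- .binPath(index@path, packed)
  if (!file.exists(f)) return(.binToDf(NULL))
  payload <- tryCatch(readRDS(f), error = function(e)
    stop("integrity error: corrupted bin file ", f, " (", conditionMessage(e), ")"))
  if (!identical(payload$v, .SCHEMA_VERSION))
    stop("integrity error: unsupported bin schema in ", f)
  .binToDf(payload)
}

#' Corpus statistics of an index
#'
#' Per-bin structure and occurrence counts, sorted descending by the
#' number of structures containing the residue pair (ties broken by
#' occurrence count, then key).
#'
#' @param index A \linkS4class{MotifIndex}.
#' @param topN Number of rows to return (default all).
#' @return data.frame with columns descriptor, structures, occurrences.
#' @export
indexStats <- function(index, topN = Inf) {
  stopifnot(is(index, "MotifIndex"))
  files <- .listBins(index@path)
  if (!length(files))
    return(data.frame(descriptor = character(0), structures = integer(0),
                      occurrences = integer(0)))
  packed <- as.integer(sub("\\.rds$", "", basename(files)))
  nStruct <- integer(length(files))
  nOcc <- integer(length(files))
  for (k in seq_along(files)) {
    p <- readRDS(files[k])
    nStruct[k] <- length(p$structures)
    nOcc[k] <- sum(vapply(p$occ, nrow, 1L))
  }
  ord <- order(-nStruct, -nOcc, packed, method = "radix")
  out <- data.frame(descriptor = renderKey(packed[ord]),
                    structures = nStruct[ord], occurrences = nOcc[ord],
                    stringsAsFactors = FALSE)
  utils::head(out, topN)
}
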
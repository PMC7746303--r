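# Residue-pair geometric descriptors.
#
# A pair of residues is summarised by three rotation-invariant measures:
# the backbone-representative distance d_b, the sidechain-representative
# distance d_s, and the angle theta between the two backbone->sidechain
# vectors. Distances are binned at 1 A, angles at 20 deg (left-closed
# intervals, floor convention; theta = 180 clamps into bin 8). Together
# with the lexicographically sorted residue-type pair this yields a
# descriptor key, e.g. "HS-8-7-5" for a histidine/serine pair with
# d_b in [8,9) A, d_s in [7,8) A, theta in [100,120) deg, which packs
# bijectively into a single integer.

.DB_BINS <- 20L   # d_b < 20 A (indexing cutoff)
.DS_BINS <- 32L   # d_s ceiling for integer packing
.TH_BINS <- 9L    # theta in [0, 180], 20 deg bins, 180 clamps to bin 8

#' Geometry of a residue pair
#'
#' @param r1,r2 Residue records or single rows of a structure's residue
#'   table (anything carrying backbone/sidechain representative points; use
#'   \code{residueTable(structure)} rows or the records returned by
#'   \code{\link{fetchResidues}}).
#' @return List with db, ds (Angstrom) and theta (degrees, in [0, 180]).
#'   Symmetric in its arguments and invariant under rigid motion applied to
#'   both residues.
#' @export
pairGeometry <- function(r1, r2) {
  g <- .repsOf(r1); h <- .repsOf(r2)
  v1 <- g$sidechain - g$backbone
  v2 <- h$sidechain - h$backbone
  n1 <- .vnorm(v1); n2 <- .vnorm(v2)
  if (n1 < 1e-6 || n2 < 1e-6)
    stop("degenerate geometry: zero-length backbone->sidechain vector")
  cosang <- sum(v1 * v2) / (n1 * n2)
  cosang <- min(1, max(-1, cosang))
  list(db = .vnorm(g$backbone - h$backbone),
       ds = .vnorm(g$sidechain - h$sidechain),
       theta = acos(cosang) * 180 / pi)
}

#' @keywords internal
.repsOf <- function(r) {
  if (is.list(r) && !is.null(r$backbone))
    return(list(backbone = r$backbone, sidechain = r$sidechain))
  if (is.data.frame(r) && nrow(r) == 1L)
    return(list(backbone = c(r$bx, r$by, r$bz),
                sidechain = c(r$sx, r$sy, r$sz)))
  stop("cannot extract representative points from object of class ",
       class(r)[1L])
}

#' Bin a pair geometry into a descriptor key
#'
#' @param code1,code2 Residue-type tokens of the two residues (order
#'   irrelevant; the key stores them sorted).
#' @param g A geometry as returned by \code{\link{pairGeometry}}.
#' @return A descriptor key: list with typePair (2-char string, sorted),
#'   dbBin, dsBin, thetaBin, and packed (the integer encoding).
#'   Signals a condition of class "strucmotif_out_of_range" when
#'   d_b >= 20 A or the d_s bin exceeds its ceiling (such pairs are not
#'   indexed).
#' @export
#' @examples
#' g <- list(db = 8.4, ds = 7.2, theta = 105)
#' renderKey(binDescriptor("S", "H", g))  # "HS-8-7-5"
binDescriptor <- function(code1, code2, g) {
  if (g$db < 0 || g$ds < 0 || g$theta < 0 || g$theta > 180 + 1e-9)
    stop("invalid pair geometry")
  if (g$db >= .DB_BINS)
    stop(.outOfRange(sprintf("d_b %.2f A beyond the %d A indexing cutoff",
                             g$db, .DB_BINS)))
  dsBin <- as.integer(floor(g$ds))
  if (dsBin >= .DS_BINS)
    stop(.outOfRange(sprintf("d_s bin %d beyond ceiling %d", dsBin,
                             .DS_BINS - 1L)))
  dbBin <- as.integer(floor(g$db))
  thetaBin <- min(as.integer(floor(g$theta / 20)), .TH_BINS - 1L)
  alpha <- tokenAlphabet()
  i <- match(code1, alpha); j <- match(code2, alpha)
  if (is.na(i) || is.na(j))
    stop("unknown residue token: ", if (is.na(i)) code1 else code2)
  if (i > j) { k <- i; i <- j; j <- k }
  key <- list(typePair = paste0(alpha[i], alpha[j]),
              dbBin = dbBin, dsBin = dsBin, thetaBin = thetaBin)
  key$packed <- encodeKey(key)
  key
}

#' @keywords internal
.outOfRange <- function(msg) {
  structure(class = c("strucmotif_out_of_range", "error", "condition"),
            list(message = msg, call = sys.call(-1L)))
}

#' Encode / decode / render descriptor keys
#'
#' \code{encodeKey} packs a descriptor key into a single integer, strictly
#' monotone in (typePair, dbBin, dsBin, thetaBin) lexicographic order;
#' \code{decodeKey} inverts it; \code{renderKey} gives the human-readable
#' form "XY-db-ds-theta" used in logs, stats output and bin file names;
#' \code{parseKey} inverts \code{renderKey}.
#'
#' @param key A key as returned by \code{\link{binDescriptor}} (a list with
#'   typePair, dbBin, dsBin, thetaBin), or for \code{renderKey} optionally
#'   a packed integer.
#' @param packed Integer vector of packed keys.
#' @return \code{encodeKey}: integer; \code{decodeKey}: key list;
#'   \code{renderKey}: character; \code{parseKey}: key list.
#' @export
encodeKey <- function(key) {
  alpha <- tokenAlphabet()
  i <- match(substr(key$typePair, 1L, 1L), alpha)
  j <- match(substr(key$typePair, 2L, 2L), alpha)
  stopifnot(!is.na(i), !is.na(j), i <= j,
            key$dbBin >= 0L, key$dbBin < .DB_BINS,
            key$dsBin >= 0L, key$dsBin < .DS_BINS,
            key$thetaBin >= 0L, key$thetaBin < .TH_BINS)
  p <- (i - 1L) * length(alpha) + (j - 1L)
  as.integer(((p * .DB_BINS + key$dbBin) * .DS_BINS + key$dsBin) * .TH_BINS +
               key$thetaBin)
}

#' @rdname encodeKey
#' @export
decodeKey <- function(packed) {
  stopifnot(length(packed) == 1L)
  alpha <- tokenAlphabet()
  na <- length(alpha)
  if (!is.finite(packed) || packed < 0 ||
      packed >= na * na * .DB_BINS * .DS_BINS * .TH_BINS)
    stop("invalid key: packed value out of range: ", packed)
  packed <- as.integer(packed)
  thetaBin <- packed %% .TH_BINS; packed <- packed %/% .TH_BINS
  dsBin <- packed %% .DS_BINS; packed <- packed %/% .DS_BINS
  dbBin <- packed %% .DB_BINS; p <- packed %/% .DB_BINS
  i <- p %/% na + 1L; j <- p %% na + 1L
  if (i > j || i > na) stop("invalid key: no such type pair (", p, ")")
  list(typePair = paste0(alpha[i], alpha[j]), dbBin = dbBin, dsBin = dsBin,
       thetaBin = thetaBin, packed = as.integer(
         ((p * .DB_BINS + dbBin) * .DS_BINS + dsBin) * .TH_BINS + thetaBin))
}

#' @rdname encodeKey
#' @export
renderKey <- function(key) {
  if (is.numeric(key)) {
    return(vapply(key, function(k) renderKey(decodeKey(k)), ""))
  }
  sprintf("%s-%d-%d-%d", key$typePair, key$dbBin, key$dsBin, key$thetaBin)
}

#' @rdname encodeKey
#' @export
parseKey <- function(key) {
  m <- regmatches(key, regexec("^(..)-([0-9]+)-([0-9]+)-([0-9]+)$", key))[[1L]]
  if (length(m) != 5L) stop("malformed descriptor key: ", key)
  k <- list(typePair = m[2L], dbBin = as.integer(m[3L]),
            dsBin = as.integer(m[4L]), thetaBin = as.integer(m[5L]))
  k$packed <- encodeKey(k)
  k
}

#' Tolerance neighborhood of a descriptor key
#'
#' All keys with the same type pair whose three geometric bins each differ
#' from the input by at most \code{tolerance}, clamped to the valid bin
#' ranges. At tolerance 1 and away from range boundaries this is the
#' 3 x 3 x 3 = 27-key neighborhood consulted at lookup time so that
#' occurrences close to a bin border are not lost.
#'
#' @param key A descriptor key (list or packed integer).
#' @param tolerance Non-negative integer (default 1).
#' @return Integer vector of packed keys, sorted ascending.
#' @export
neighborKeys <- function(key, tolerance = 1L) {
  stopifnot(tolerance >= 0L)
  if (is.numeric(key)) key <- decodeKey(key)
  db <- seq(max(0L, key$dbBin - tolerance),
            min(.DB_BINS - 1L, key$dbBin + tolerance))
  ds <- seq(max(0L, key$dsBin - tolerance),
            min(.DS_BINS - 1L, key$dsBin + tolerance))
  th <- seq(max(0L, key$thetaBin - tolerance),
            min(.TH_BINS - 1L, key$thetaBin + tolerance))
  g <- expand.grid(th = th, ds = ds, db = db)
  alpha <- tokenAlphabet()
  i <- match(substr(key$typePair, 1L, 1L), alpha)
  j <- match(substr(key$typePair, 2L, 2L), alpha)
  p <- (i - 1L) * length(alpha) + (j - 1L)
  sort(as.integer(((p * .DB_BINS + g$db) * .DS_BINS + g$ds) * .TH_BINS + g$th))
}

#' Enumerate indexed residue pairs of a structure
#'
#' Yields one record per unordered residue pair with backbone distance
#' below the cutoff, intra- and inter-chain and across assembly copies.
#' Pairs whose geometry is degenerate (zero-length representative vector)
#' or whose d_s bin exceeds the packing ceiling are skipped and counted.
#'
#' @param structure A \linkS4class{PolymerStructure}.
#' @param cutoff Backbone-distance cutoff in Angstrom (default 20; pairs at
#'   or beyond it are not indexed).
#' @return data.frame with columns key (packed descriptor), chain1,
#'   operator1, seq1, chain2, operator2, seq2 (the occurrence, canonically
#'   ordered first < second), and flag (1 when the first locator's residue
#'   carries the first token of the sorted type pair). Attribute "skipped"
#'   counts pairs dropped per reason.
#' @export
enumeratePairs <- function(structure, cutoff = 20) {
  res <- structure@residues
  n <- nrow(res)
  empty <- data.frame(key = integer(0), chain1 = character(0),
                      operator1 = character(0), seq1 = integer(0),
                      chain2 = character(0), operator2 = character(0),
                      seq2 = integer(0), flag = integer(0),
                      stringsAsFactors = FALSE)
  attr(empty, "skipped") <- c(degenerate = 0L, out_of_range = 0L)
  if (n < 2L) return(empty)

  B <- as.matrix(res[, c("bx", "by", "bz")])
  S <- as.matrix(res[, c("sx", "sy", "sz")])
  V <- S - B
  vn <- sqrt(rowSums(V * V))

  d <- as.matrix(stats::dist(B))
  pair <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  if (!nrow(pair)) return(empty)
  i <- pair[, 1L]; j <- pair[, 2L]

  degen <- vn[i] < 1e-6 | vn[j] < 1e-6
  nDegen <- sum(degen)
  i <- i[!degen]; j <- j[!degen]
  if (!length(i)) {
    attr(empty, "skipped") <- c(degenerate = nDegen, out_of_range = 0L)
    return(empty)
  }
  db <- d[cbind(i, j)]
  dsv <- S[i, , drop = FALSE] - S[j, , drop = FALSE]
  ds <- sqrt(rowSums(dsv * dsv))
  cosang <- rowSums(V[i, , drop = FALSE] * V[j, , drop = FALSE]) / (vn[i] * vn[j])
  theta <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi

  dbBin <- as.integer(floor(db))
  dsBin <- as.integer(floor(ds))
  thBin <- pmin(as.integer(floor(theta / 20)), .TH_BINS - 1L)
  oor <- dsBin >= .DS_BINS | dbBin >= .DB_BINS
  nOor <- sum(oor)
  keep <- !oor
  i <- i[keep]; j <- j[keep]
  dbBin <- dbBin[keep]; dsBin <- dsBin[keep]; thBin <- thBin[keep]

  alpha <- tokenAlphabet()
  ti <- match(res$code[i], alpha); tj <- match(res$code[j], alpha)
  lo <- pmin(ti, tj); hi <- pmax(ti, tj)
  p <- (lo - 1L) * length(alpha) + (hi - 1L)
  key <- as.integer(((p * .DB_BINS + dbBin) * .DS_BINS + dsBin) * .TH_BINS + thBin)

  # canonical occurrence order: first < second under the locator order
  swap <- !.locatorLess(res$chain[i], res$operator[i], res$seq[i],
                        res$chain[j], res$operator[j], res$seq[j])
  a <- ifelse(swap, j, i); b <- ifelse(swap, i, j)
  firstTok <- match(res$code[a], alpha)
  flag <- as.integer(firstTok == lo)

  out <- data.frame(key = key,
                    chain1 = res$chain[a], operator1 = res$operator[a],
                    seq1 = res$seq[a],
                    chain2 = res$chain[b], operator2 = res$operator[b],
                    seq2 = res$seq[b], flag = flag, stringsAsFactors = FALSE)
  ord <- order(out$key, out$chain1, out$operator1, out$seq1,
               out$chain2, out$operator2, out$seq2, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- c(degenerate = nDegen, out_of_range = nOor)
  out
}
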
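# Hit scoring: atom correspondence between query and candidate residues,
# quaternion-based least-squares superposition, and RMSD filtering/sorting.

#' Atom correspondence between a query and a hit residue
#'
#' Pairs atoms by name. With \code{mode = "all"} every heavy-atom name
#' present in both residues is paired; \code{"sidechain"} restricts to
#' non-backbone names (for amino acids everything but N/CA/C/O/OXT, for
#' nucleotides the base atoms); \code{"representatives"} pairs exactly the
#' backbone and sidechain representative points. When residue types differ
#' (an exchange matched), only the shared names pair; no attempt is made to
#' resolve chemically ambiguous name symmetry (e.g. the two ring branches
#' of a tyrosine).
#'
#' @param queryResidue,hitResidue Residue records (as returned by
#'   \code{\link{fetchResidues}} or held in a \linkS4class{MotifQuery}).
#' @param mode "all", "sidechain" or "representatives".
#' @return List with matrices \code{query} and \code{hit} (paired
#'   coordinates, same row order) and \code{names}; zero rows when no name
#'   is shared.
#' @export
atomCorrespondence <- function(queryResidue, hitResidue,
                               mode = c("all", "sidechain", "representatives")) {
  mode <- match.arg(mode)
  if (mode == "representatives") {
    q <- rbind(queryResidue$backbone, queryResidue$sidechain)
    h <- rbind(hitResidue$backbone, hitResidue$sidechain)
    return(list(query = q, hit = h, names = c("<backbone>", "<sidechain>")))
  }
  qn <- rownames(queryResidue$atoms)
  hn <- rownames(hitResidue$atoms)
  shared <- sort(intersect(qn, hn), method = "radix")
  if (mode == "sidechain")
    shared <- shared[!.isBackboneAtom(shared, queryResidue$kind)]
  list(query = queryResidue$atoms[shared, , drop = FALSE],
       hit = hitResidue$atoms[shared, , drop = FALSE],
       names = shared)
}

#' Optimal superposition RMSD (quaternion method)
#'
#' Computes the global minimum root-mean-square deviation over all proper
#' rigid transforms, via the largest eigenvalue of the 4x4 quaternion key
#' matrix, together with the optimising transform mapping the hit
#' coordinates onto the query.
#'
#' @param query,hit Numeric n x 3 matrices of paired coordinates (n >= 3,
#'   not all collinear).
#' @return List with rmsd (Angstrom), rotation (3x3, proper), translation
#'   (length 3): \code{rotation \%*\% hit_i + translation ~ query_i}.
#' @export
superposeRmsd <- function(query, hit) {
  query <- as.matrix(query); hit <- as.matrix(hit)
  if (nrow(query) != nrow(hit)) stop("pairing length mismatch")
  if (nrow(query) < 3L)
    stop("degenerate superposition: need at least 3 point pairs")
  if (.isCollinear(query) || .isCollinear(hit))
    stop("degenerate superposition: collinear point set")
  fit <- .quaternionSuperpose(hit, query)
  list(rmsd = fit$rmsd, rotation = fit$rotation, translation = fit$translation)
}

#' @keywords internal
.isCollinear <- function(m) {
  c0 <- sweep(m, 2L, colMeans(m))
  s <- svd(c0, nu = 0L, nv = 0L)$d
  s[2L] < 1e-9 * max(s[1L], 1e-12)
}

#' Score assembled candidates
#'
#' Fetches only the candidate residues from the coordinate store, builds
#' the atom pairing role by role, superposes, filters by the optional RMSD
#' cutoff and returns hits sorted ascending by RMSD (ties by structure id,
#' then rendered assignment). Candidates yielding fewer than 3 atom pairs
#' are skipped with a warning.
#'
#' @param candidates Candidate table from \code{\link{assembleCandidates}}.
#' @param query The \linkS4class{MotifQuery}.
#' @param index A \linkS4class{MotifIndex} (for its coordinate store), or a
#'   store directory path.
#' @param rmsdCutoff Optional cutoff in Angstrom.
#' @param atomMode "sidechain" (default), "all" or "representatives".
#' @return data.frame: structure_id, assignment (rendered locators in role
#'   order, comma-separated), rmsd, atom_count, atom_mode, and the 12
#'   transform components r11..r33, tx, ty, tz (hit -> query).
#' @export
scoreCandidates <- function(candidates, query, index, rmsdCutoff = NULL,
                            atomMode = c("sidechain", "all", "representatives")) {
  atomMode <- match.arg(atomMode)
  nRoles <- nrow(query@residues)
  roleCols <- paste0("role", seq_len(nRoles))
  empty <- data.frame(structure_id = character(0), assignment = character(0),
                      rmsd = numeric(0), atom_count = integer(0),
                      atom_mode = character(0), stringsAsFactors = FALSE)
  tcols <- c(paste0("r", c("11", "12", "13", "21", "22", "23", "31", "32", "33")),
             "tx", "ty", "tz")
  for (cn in tcols) empty[[cn]] <- numeric(0)
  if (!nrow(candidates)) return(empty)

  out <- vector("list", nrow(candidates))
  skipped <- 0L
  for (i in seq_len(nrow(candidates))) {
    sid <- candidates$sid[i]
    locs <- unlist(candidates[i, roleCols], use.names = FALSE)
    residues <- fetchResidues(index, sid, as.list(locs))
    qs <- list(); hs <- list(); npairs <- 0L
    for (r in seq_len(nRoles)) {
      pr <- atomCorrespondence(query@refResidues[[r]], residues[[r]], atomMode)
      if (nrow(pr$query)) {
        qs[[length(qs) + 1L]] <- pr$query
        hs[[length(hs) + 1L]] <- pr$hit
        npairs <- npairs + nrow(pr$query)
      }
    }
    if (npairs < 3L) {
      skipped <- skipped + 1L
      next
    }
    fit <- tryCatch(superposeRmsd(do.call(rbind, qs), do.call(rbind, hs)),
                    error = function(e) NULL)
    if (is.null(fit)) { skipped <- skipped + 1L; next }
    if (!is.null(rmsdCutoff) && fit$rmsd > rmsdCutoff) next
    row <- data.frame(structure_id = sid,
                      assignment = paste(locs, collapse = ","),
                      rmsd = fit$rmsd, atom_count = npairs,
                      atom_mode = atomMode, stringsAsFactors = FALSE)
    tv <- c(t(fit$rotation), fit$translation)
    for (k in seq_along(tcols)) row[[tcols[k]]] <- tv[k]
    out[[i]] <- row
  }
  if (skipped)
    warning(skipped, " candidate(s) skipped: empty or degenerate atom correspondence")
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty)
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$rmsd, hits$structure_id, hits$assignment,
                     method = "radix"), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write a hit table
#'
#' @param hits Hit table from \code{\link{runSearch}}.
#' @param path Output path; format by extension: ".csv" or ".jsonl" (JSON
#'   lines).
#' @param digits RMSD decimals in CSV output (default 3).
#' @return \code{path}, invisibly.
#' @export
writeHits <- function(hits, path, digits = 3L) {
  if (grepl("\\.jsonl$", path)) {
    con <- file(path, "wt")
    on.exit(close(con))
    for (i in seq_len(nrow(hits)))
      writeLines(jsonlite::toJSON(as.list(hits[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
  } else {
    h2 <- hits
    h2$rmsd <- round(h2$rmsd, digits)
    utils::write.csv(h2, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}
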
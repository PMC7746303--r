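# Motif query definition, edge pruning and candidate assembly.
#
# A query is a small set of residue roles taken from a reference structure,
# each with one or more allowed residue tokens (position-specific
# exchanges). All admissible role pairs (backbone distance < 20 A) carry
# the reference geometry; queries with 4+ residues are pruned to the n-1
# edges of a minimum spanning tree (Kruskal on the backbone distance,
# deterministic tie-break by role-index pair) so that fewer bins must be
# read. Candidates are assembled per structure by joining the retrieved
# occurrences along the query edges; geometric deviation in pairs omitted
# by the pruning shows up in the RMSD stage rather than being re-checked.

#' Define a motif query from a reference structure
#'
#' @param reference A \linkS4class{PolymerStructure}.
#' @param selectors Residue selectors (see \code{\link{selectResidues}}),
#'   in role order.
#' @param exchanges Named list mapping role index (as character or integer
#'   position) to additional allowed residue tokens, e.g.
#'   \code{list("1" = "H", "4" = c("D", "N"))}.
#' @param numbering Selector numbering, "label" or "auth".
#' @return A \linkS4class{MotifQuery}.
#' @export
defineQuery <- function(reference, selectors, exchanges = list(),
                        numbering = c("label", "auth")) {
  numbering <- match.arg(numbering)
  if (length(selectors) < 2L) stop("a motif query needs at least 2 residues")
  sel <- selectResidues(reference, selectors, numbering = numbering)
  n <- nrow(sel)
  roles <- data.frame(role = seq_len(n), chain = sel$chain,
                      operator = sel$operator, seq = sel$seq,
                      code = sel$code, stringsAsFactors = FALSE)
  allowed <- lapply(seq_len(n), function(i) {
    extra <- exchanges[[as.character(i)]]
    if (is.null(extra) && !is.null(names(exchanges)))
      extra <- character(0)
    else if (is.null(names(exchanges)) && length(exchanges) >= i)
      extra <- exchanges[[i]]
    toks <- unique(c(sel$code[i], extra))
    bad <- setdiff(toks, tokenAlphabet())
    if (length(bad)) stop("unknown exchange token(s): ", paste(bad, collapse = ", "))
    toks
  })
  refResidues <- lapply(sel$row, function(r) .residueRecord(reference, r))

  combs <- utils::combn(n, 2L)
  pairs <- data.frame(a = combs[1L, ], b = combs[2L, ], db = NA_real_,
                      ds = NA_real_, theta = NA_real_)
  for (k in seq_len(ncol(combs))) {
    g <- pairGeometry(refResidues[[combs[1L, k]]], refResidues[[combs[2L, k]]])
    pairs$db[k] <- g$db; pairs$ds[k] <- g$ds; pairs$theta[k] <- g$theta
  }
  admissible <- pairs[pairs$db < .DB_BINS, , drop = FALSE]
  # the graph of admissible pairs must connect all roles
  comp <- .connectedComponents(n, admissible$a, admissible$b)
  if (length(unique(comp)) > 1L)
    stop("motif too extended: roles ",
         paste(which(comp != comp[1L]), collapse = ", "),
         " are beyond the 20 A backbone cutoff from the rest of the motif")
  if (nrow(admissible) < nrow(pairs))
    warning(sprintf("%d role pair(s) beyond the 20 A cutoff excluded from edge candidates",
                    nrow(pairs) - nrow(admissible)))
  rownames(admissible) <- NULL
  new("MotifQuery", referenceId = reference@structureId, residues = roles,
      allowed = allowed, refResidues = refResidues, pairs = admissible)
}

#' @keywords internal
.connectedComponents <- function(n, a, b) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, 1L)
}

#' Prune query edges
#'
#' Motifs with 2 or 3 residues keep all admissible pairs; motifs with 4 or
#' more residues are pruned to the minimum spanning tree of the pair graph
#' (Kruskal's algorithm, edge weight = reference backbone distance, ties
#' broken by the role-index pair), leaving n - 1 edge constraints.
#'
#' @param query A \linkS4class{MotifQuery}.
#' @return data.frame of edges: a, b, db, ds, theta.
#' @export
fragmentQuery <- function(query) {
  edges <- query@pairs
  n <- nrow(query@residues)
  if (n <= 3L) return(edges)
  ord <- order(edges$db, edges$a, edges$b, method = "radix")
  edges <- edges[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  keep <- logical(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges$a[k]); rb <- find(edges$b[k])
    if (ra != rb) { parent[ra] <- rb; keep[k] <- TRUE }
  }
  out <- edges[keep, , drop = FALSE]
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# keys to read for one edge: cross-product of the two roles' allowed
# tokens, each expanded by the tolerance neighborhood; every row keeps the
# (tokenA, tokenB) combination that generated it so that retrieved
# occurrences can be oriented onto the roles.
#' @keywords internal
.edgeKeyTable <- function(query, edge, tolerance) {
  g <- list(db = edge$db, ds = edge$ds, theta = edge$theta)
  toksA <- query@allowed[[edge$a]]
  toksB <- query@allowed[[edge$b]]
  combos <- expand.grid(ta = toksA, tb = toksB, stringsAsFactors = FALSE)
  parts <- lapply(seq_len(nrow(combos)), function(k) {
    key <- binDescriptor(combos$ta[k], combos$tb[k], g)
    data.frame(packed = neighborKeys(key, tolerance),
               ta = combos$ta[k], tb = combos$tb[k],
               stringsAsFactors = FALSE)
  })
  unique(do.call(rbind, parts))
}

#' Assemble candidate assignments from the index
#'
#' For every structure whose postings contain all query edges, enumerates
#' every injective role-to-locator assignment such that each edge is
#' witnessed by a retrieved occurrence with compatible residue tokens.
#' Structures lacking any edge's postings are rejected without further
#' work.
#'
#' @param index A \linkS4class{MotifIndex}.
#' @param query A \linkS4class{MotifQuery}.
#' @param edges Edge table from \code{\link{fragmentQuery}} (computed if
#'   missing).
#' @param tolerance Bin tolerance per geometric measure (default 1).
#' @return data.frame of candidates: sid plus one rendered-locator column
#'   per role (role1, role2, ...), deterministic and duplicate-free.
#'   Attribute "report": structures touched vs rejected.
#' @export
assembleCandidates <- function(index, query, edges = NULL, tolerance = 1L) {
  if (is.null(edges)) edges <- fragmentQuery(query)
  stopifnot(nrow(edges) >= 1L)
  nRoles <- nrow(query@residues)

  # per edge: sid -> oriented locator pairs (role a locator, role b locator)
  edgePost <- vector("list", nrow(edges))
  for (e in seq_len(nrow(edges))) {
    keys <- .edgeKeyTable(query, edges[e, ], tolerance)
    parts <- list()
    for (packed in unique(keys$packed)) {
      post <- lookupBin(index, packed)
      if (!nrow(post)) next
      tp <- decodeKey(packed)$typePair
      t1 <- substr(tp, 1L, 1L); t2 <- substr(tp, 2L, 2L)
      rows <- keys[keys$packed == packed, , drop = FALSE]
      for (k in seq_len(nrow(rows))) {
        ta <- rows$ta[k]; tb <- rows$tb[k]
        if (ta == tb) {
          parts[[length(parts) + 1L]] <- data.frame(
            sid = post$sid,
            la = renderLocator(post$chain1, post$operator1, post$seq1),
            lb = renderLocator(post$chain2, post$operator2, post$seq2),
            stringsAsFactors = FALSE)
          parts[[length(parts) + 1L]] <- data.frame(
            sid = post$sid,
            la = renderLocator(post$chain2, post$operator2, post$seq2),
            lb = renderLocator(post$chain1, post$operator1, post$seq1),
            stringsAsFactors = FALSE)
        } else {
          # flag == 1: the first locator carries the first (sorted) token
          aIsFirst <- if (ta == t1) post$flag == 1L else post$flag == 0L
          parts[[length(parts) + 1L]] <- data.frame(
            sid = post$sid,
            la = ifelse(aIsFirst,
                        renderLocator(post$chain1, post$operator1, post$seq1),
                        renderLocator(post$chain2, post$operator2, post$seq2)),
            lb = ifelse(aIsFirst,
                        renderLocator(post$chain2, post$operator2, post$seq2),
                        renderLocator(post$chain1, post$operator1, post$seq1)),
            stringsAsFactors = FALSE)
        }
      }
    }
    ep <- if (length(parts)) unique(do.call(rbind, parts))
          else data.frame(sid = character(0), la = character(0),
                          lb = character(0), stringsAsFactors = FALSE)
    edgePost[[e]] <- ep
  }

  touched <- sort(unique(unlist(lapply(edgePost, function(p) p$sid))))
  candidateSids <- touched
  for (p in edgePost) candidateSids <- intersect(candidateSids, unique(p$sid))
  rejected <- setdiff(touched, candidateSids)

  # join edges per structure by backtracking over roles
  edgeOrder <- .edgeJoinOrder(nRoles, edges)
  results <- list()
  for (sid in sort(candidateSids)) {
    perEdge <- lapply(edgePost, function(p) p[p$sid == sid, c("la", "lb")])
    partials <- list(rep(NA_character_, nRoles))
    ok <- TRUE
    for (e in edgeOrder) {
      pr <- perEdge[[e]]
      a <- edges$a[e]; b <- edges$b[e]
      nxt <- list()
      for (asg in partials) {
        haveA <- !is.na(asg[a]); haveB <- !is.na(asg[b])
        if (haveA && haveB) {
          if (any(pr$la == asg[a] & pr$lb == asg[b]))
            nxt[[length(nxt) + 1L]] <- asg
        } else if (haveA) {
          for (lb in unique(pr$lb[pr$la == asg[a]])) {
            if (lb %in% asg) next  # injectivity
            a2 <- asg; a2[b] <- lb
            nxt[[length(nxt) + 1L]] <- a2
          }
        } else if (haveB) {
          for (la in unique(pr$la[pr$lb == asg[b]])) {
            if (la %in% asg) next
            a2 <- asg; a2[a] <- la
            nxt[[length(nxt) + 1L]] <- a2
          }
        } else {
          for (k in seq_len(nrow(pr))) {
            if (pr$la[k] == pr$lb[k]) next
            a2 <- asg; a2[a] <- pr$la[k]; a2[b] <- pr$lb[k]
            nxt[[length(nxt) + 1L]] <- a2
          }
        }
      }
      partials <- unique(nxt)
      if (!length(partials)) { ok <- FALSE; break }
    }
    if (!ok) { rejected <- c(rejected, sid); next }
    complete <- Filter(function(asg) !anyNA(asg), partials)
    if (!length(complete)) { rejected <- c(rejected, sid); next }
    mat <- do.call(rbind, complete)
    results[[sid]] <- data.frame(sid = sid, mat, stringsAsFactors = FALSE)
  }

  out <- if (length(results)) do.call(rbind, results)
         else data.frame(sid = character(0),
                         matrix(character(0), 0L, nRoles),
                         stringsAsFactors = FALSE)
  names(out) <- c("sid", paste0("role", seq_len(nRoles)))
  if (nrow(out)) {
    out <- unique(out)
    out <- out[do.call(order, c(unname(out), list(method = "radix"))), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "report") <- list(touched = length(touched),
                              rejected = length(unique(rejected)),
                              assembled = length(unique(out$sid)))
  out
}

# order edges so each one (after the first) shares a role with an earlier
# edge; holds for MSTs and for complete pair sets alike
#' @keywords internal
.edgeJoinOrder <- function(nRoles, edges) {
  remaining <- seq_len(nrow(edges))
  covered <- integer(0)
  ord <- integer(0)
  while (length(remaining)) {
    pick <- NA_integer_
    for (e in remaining) {
      if (!length(covered) || edges$a[e] %in% covered || edges$b[e] %in% covered) {
        pick <- e; break
      }
    }
    if (is.na(pick)) pick <- remaining[1L]  # disconnected edge set
    ord <- c(ord, pick)
    covered <- union(covered, c(edges$a[pick], edges$b[pick]))
    remaining <- setdiff(remaining, pick)
  }
  ord
}

#' Run a motif search end to end
#'
#' Retrieves postings for the (pruned) query edges, assembles candidates
#' per structure, fetches only the candidate residues from the coordinate
#' store, scores each candidate by quaternion least-squares RMSD, filters
#' by the cutoff and returns hits sorted ascending by RMSD (ties by
#' structure id, then assignment).
#'
#' @param index A \linkS4class{MotifIndex}.
#' @param query A \linkS4class{MotifQuery}.
#' @param tolerance Bin tolerance (default 1).
#' @param rmsdCutoff Drop hits with RMSD above this value (Angstrom);
#'   \code{NULL} keeps all.
#' @param atomMode Atom set for scoring: "sidechain" (default), "all" or
#'   "representatives".
#' @param maxHits Truncate the sorted hit list (default unlimited).
#' @return data.frame of hits (see \code{\link{scoreCandidates}});
#'   attribute "report" records structures touched, rejected and scored
#'   plus the search parameters.
#' @export
runSearch <- function(index, query, tolerance = 1L, rmsdCutoff = NULL,
                      atomMode = c("sidechain", "all", "representatives"),
                      maxHits = NULL) {
  atomMode <- match.arg(atomMode)
  stopifnot(is(index, "MotifIndex"))
  if (!is.null(rmsdCutoff)) stopifnot(rmsdCutoff > 0)
  edges <- fragmentQuery(query)
  cands <- assembleCandidates(index, query, edges, tolerance)
  hits <- scoreCandidates(cands, query, index, rmsdCutoff = rmsdCutoff,
                          atomMode = atomMode)
  if (!is.null(maxHits) && nrow(hits) > maxHits)
    hits <- hits[seq_len(maxHits), , drop = FALSE]
  rpt <- attr(cands, "report")
  rpt$scored <- nrow(hits)
  rpt$parameters <- list(tolerance = tolerance,
                         rmsd_cutoff = rmsdCutoff, atom_mode = atomMode,
                         max_hits = maxHits)
  attr(hits, "report") <- rpt
  hits
}
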
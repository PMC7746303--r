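# Query definition, MST pruning, candidate assembly, end-to-end search.

test_that("query definition captures roles, exchanges and admissible pairs", {
  q <- triadQuery()
  expect_equal(nResidues(q), 3L)
  expect_equal(residueTable(q)$code, c("H", "D", "S"))
  expect_equal(nrow(q@pairs), 3L)

  # exchanges extend the allowed token sets per role
  ref <- motifAsStructure(syntheticTriadMotif())
  q2 <- defineQuery(ref, c("A-1", "A-2", "A-3"),
                    exchanges = list("1" = "K", "3" = c("T", "C")))
  expect_equal(q2@allowed, list(c("H", "K"), "D", c("S", "T", "C")))
  expect_error(defineQuery(ref, c("A-1", "A-2", "A-3"),
                           exchanges = list("1" = "Z")), "unknown exchange")
  expect_error(defineQuery(ref, "A-1"), "at least 2")
})

test_that("queries whose residues exceed the cutoff are rejected", {
  far <- list(
    strucmotif:::.syntheticResidue("H", c(0, 0, 0), c(0, 0, 1), seq = 1L),
    strucmotif:::.syntheticResidue("S", c(30, 0, 0), c(0, 0, 1), seq = 2L))
  ref <- motifAsStructure(far, "FAR")
  expect_error(defineQuery(ref, c("A-1", "A-2")), "motif too extended")
})

test_that("edge pruning keeps all pairs below 4 residues and the MST above", {
  q2 <- defineQuery(motifAsStructure(syntheticTriadMotif()[c(1, 3)]),
                    c("A-1", "A-2"))
  expect_equal(nrow(fragmentQuery(q2)), 1L)
  expect_equal(nrow(fragmentQuery(triadQuery())), 3L)

  # five roles in a row, 6 A apart: 10 pairs reduce to 4 tree edges
  recs <- lapply(1:5, function(i)
    strucmotif:::.syntheticResidue(c("K", "D", "D", "D", "E")[i],
                                   c(6 * (i - 1), 0, 0), c(0, 1, 0), seq = i))
  expect_warning(
    q5 <- defineQuery(motifAsStructure(recs, "PENTA"), paste0("A-", 1:5)),
    "beyond the 20 A cutoff")
  expect_equal(nrow(q5@pairs), 9L)  # the 24 A end pair is inadmissible
  edges <- fragmentQuery(q5)
  expect_equal(nrow(edges), 4L)
  # chain MST: consecutive links are the shortest spanning set
  expect_equal(edges$a, 1:4)
  expect_equal(edges$b, 2:5)
  # every role covered
  expect_setequal(unique(c(edges$a, edges$b)), 1:5)
  # deterministic under repetition
  expect_identical(fragmentQuery(q5), edges)
})

test_that("assembly finds exactly the planted instance and honors injectivity", {
  corpus <- smallCorpus(n = 6, planted = 1, seed = 29)
  idx <- buildIndex(corpus$dir, tempfile("idx"))
  q <- triadQuery()
  cands <- assembleCandidates(idx, q, tolerance = 1L)
  truthLoc <- renderLocator(corpus$truth$chain, corpus$truth$operator,
                            corpus$truth$seq)
  planted <- paste(truthLoc, collapse = ",")
  got <- packageCandidates(cands, corpus$truth$structure_id[1], 3L)
  expect_true(planted %in% got)
  # every candidate assignment is injective
  for (r in seq_len(nrow(cands)))
    expect_equal(anyDuplicated(unlist(cands[r, paste0("role", 1:3)])), 0L)
  rpt <- attr(cands, "report")
  expect_gte(rpt$rejected, 0L)
  expect_equal(rpt$assembled, length(unique(cands$sid)))
})

test_that("index-backed candidates equal the brute-force enumeration", {
  corpus <- smallCorpus(n = 8, planted = 3, seed = 37, nResidues = c(25L, 60L))
  structs <- lapply(corpus$files, loadStructure)
  idx <- buildIndex(structs, tempfile("idx"))
  q <- triadQuery()
  edges <- fragmentQuery(q)
  for (tol in 0:2) {
    cands <- assembleCandidates(idx, q, edges, tolerance = tol)
    for (s in structs) {
      want <- oracleCandidates(s, edges, q@allowed, tol)
      got <- packageCandidates(cands, structureId(s), 3L)
      expect_identical(got, want)
    }
  }
})

test_that("rejection is sound: rejected structures contain no oracle match", {
  corpus <- smallCorpus(n = 6, planted = 2, seed = 61)
  structs <- lapply(corpus$files, loadStructure)
  idx <- buildIndex(structs, tempfile("idx"))
  q <- triadQuery()
  edges <- fragmentQuery(q)
  cands <- assembleCandidates(idx, q, edges, tolerance = 1L)
  accepted <- unique(cands$sid)
  for (s in structs) {
    if (structureId(s) %in% accepted) next
    expect_length(oracleCandidates(s, edges, q@allowed, 1L), 0L)
  }
})

test_that("hit sets grow monotonically with tolerance", {
  corpus <- smallCorpus(n = 8, planted = 3, sigma = 0.1, seed = 43)
  idx <- buildIndex(corpus$dir, tempfile("idx"))
  q <- triadQuery()
  prev <- character(0)
  for (tol in 0:2) {
    h <- runSearch(idx, q, tolerance = tol, rmsdCutoff = 1)
    cur <- paste(h$structure_id, h$assignment)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("MST pruning loses no hits relative to the full edge set", {
  # n = 4 motif so pruning actually bites: triad plus one glutamate
  motif4 <- c(syntheticTriadMotif(),
              list(strucmotif:::.syntheticResidue("E", c(4.5, -4.5, 2),
                                                  c(0, -0.8, 0.6), seq = 4L)))
  corpus <- makeBenchmarkCorpus(8, 3, motif = motif4, sigma = 0.05, seed = 83,
                                dir = tempfile("c4"), nResidues = c(25L, 50L))
  idx <- buildIndex(corpus$dir, tempfile("idx"))
  q <- defineQuery(motifAsStructure(motif4), paste0("A-", 1:4))
  expect_equal(nrow(q@pairs), 6L)
  mstEdges <- fragmentQuery(q)
  expect_equal(nrow(mstEdges), 3L)
  full <- assembleCandidates(idx, q, q@pairs, tolerance = 1L)
  mst <- assembleCandidates(idx, q, mstEdges, tolerance = 1L)
  fullSet <- apply(full[, -1, drop = FALSE], 1, paste, collapse = ",")
  mstSet <- apply(mst[, -1, drop = FALSE], 1, paste, collapse = ",")
  expect_true(all(fullSet %in% mstSet))
})

test_that("self-search returns the query itself at the rounding floor", {
  ref <- motifAsStructure(syntheticTriadMotif(), "SELF")
  idx <- buildIndex(list(ref), tempfile("idx"))
  q <- defineQuery(ref, c("A-1", "A-2", "A-3"))
  h <- runSearch(idx, q, tolerance = 1)
  expect_equal(nrow(h), 1L)
  expect_equal(h$structure_id, "SELF")
  expect_equal(h$assignment, "A_1-1,A_1-2,A_1-3")
  # bounded by the 0.1 A coordinate rounding of the store
  expect_lte(h$rmsd, 0.12)
})

test_that("search results are deterministic and correctly ordered", {
  corpus <- smallCorpus(n = 8, planted = 4, sigma = 0.2, seed = 101)
  idx <- buildIndex(corpus$dir, tempfile("idx"))
  q <- triadQuery()
  h1 <- runSearch(idx, q, tolerance = 1)
  h2 <- runSearch(idx, q, tolerance = 1)
  expect_identical(h1, h2)
  expect_true(all(diff(h1$rmsd) >= 0))
  h3 <- runSearch(idx, q, tolerance = 1, maxHits = 2)
  expect_lte(nrow(h3), 2L)
  expect_identical(h3$assignment, h1$assignment[seq_len(nrow(h3))])
})
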
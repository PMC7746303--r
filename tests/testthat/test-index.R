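# Inverted-index persistence: build, lookup, incremental update,
# statistics, coordinate store.

test_that("build on an empty corpus yields an empty but valid index", {
  idx <- buildIndex(list(), tempfile("idx"))
  m <- indexManifest(idx)
  expect_equal(m$total_pairs, 0L)
  expect_equal(m$bin_count, 0L)
  expect_length(m$indexed, 0L)
  expect_equal(nrow(indexStats(idx)), 0L)
  expect_equal(nrow(lookupBin(idx, "HS-8-7-5")), 0L)
})

test_that("a three-residue structure indexes its three pairs", {
  s <- motifAsStructure(syntheticTriadMotif(), "TRIAD")
  idx <- buildIndex(list(s), tempfile("idx"))
  m <- indexManifest(idx)
  expect_equal(m$total_pairs, 3L)
  expect_lte(m$bin_count, 3L)
  expect_named(m$indexed, "TRIAD")
  # the His/Ser pair sits in its advertised bin
  post <- lookupBin(idx, "HS-8-7-5")
  expect_equal(nrow(post), 1L)
  expect_equal(post$sid, "TRIAD")
  expect_equal(renderLocator(post$chain1, post$operator1, post$seq1), "A_1-1")
  expect_equal(renderLocator(post$chain2, post$operator2, post$seq2), "A_1-3")
})

test_that("per-bin counts equal a brute-force recount over the corpus", {
  corpus <- smallCorpus(n = 6, planted = 0, seed = 41)
  structs <- lapply(corpus$files, loadStructure)
  idx <- buildIndex(structs, tempfile("idx"))
  # recount from the oracle enumeration
  recount <- new.env()
  for (s in structs) {
    op <- oraclePairs(s)
    keys <- sprintf("%s-%d-%d-%d", op$typePair, op$db, op$ds, op$theta)
    for (k in keys) {
      cur <- mget(k, recount, ifnotfound = 0L)[[1]]
      assign(k, cur + 1L, recount)
    }
  }
  st <- indexStats(idx)
  expect_equal(sum(st$occurrences), indexManifest(idx)$total_pairs)
  expect_equal(nrow(st), length(ls(recount)))
  for (r in seq_len(nrow(st)))
    expect_equal(st$occurrences[r], get(st$descriptor[r], recount))
  # sorted descending by structures, ties by occurrences then key
  expect_true(all(diff(st$structures) <= 0))
})

test_that("duplicate ids and existing destinations are rejected", {
  s <- generateStructure(5, seed = 1, structureId = "DUP")
  expect_error(buildIndex(list(s, s), tempfile("idx")), "duplicate structure_id")
  d <- tempfile("idx"); dir.create(d)
  expect_error(buildIndex(list(s), d), "already exists")
})

test_that("incremental update is bin-for-bin identical to a union rebuild", {
  corpus <- smallCorpus(n = 8, planted = 2, seed = 57)
  structs <- lapply(corpus$files, loadStructure)
  full <- buildIndex(structs, tempfile("full"))
  part <- buildIndex(structs[1:5], tempfile("part"))
  # update with zero structures is a no-op
  m0 <- indexManifest(part)
  part <- updateIndex(part, list())
  expect_equal(indexManifest(part)$total_pairs, m0$total_pairs)
  part <- updateIndex(part, structs[6:8])

  mf <- indexManifest(full); mp <- indexManifest(part)
  expect_equal(mp$total_pairs, mf$total_pairs)
  expect_equal(mp$bin_count, mf$bin_count)
  expect_setequal(names(mp$indexed), names(mf$indexed))
  binsF <- list.files(file.path(indexPath(full), "bins"), recursive = TRUE)
  binsP <- list.files(file.path(indexPath(part), "bins"), recursive = TRUE)
  expect_setequal(binsF, binsP)
  for (b in binsF)
    expect_identical(readRDS(file.path(indexPath(part), "bins", b)),
                     readRDS(file.path(indexPath(full), "bins", b)))
})

test_that("id collisions require the replace flag, which swaps occurrences", {
  s1 <- generateStructure(10, seed = 2, structureId = "X")
  s2 <- generateStructure(12, seed = 3, structureId = "X")
  idx <- buildIndex(list(s1), tempfile("idx"))
  expect_error(updateIndex(idx, list(s2)), "already indexed")
  idx <- updateIndex(idx, list(s2), replace = TRUE)
  fresh <- buildIndex(list(s2), tempfile("fresh"))
  expect_equal(indexManifest(idx)$total_pairs,
               indexManifest(fresh)$total_pairs)
  st1 <- indexStats(idx); st2 <- indexStats(fresh)
  expect_equal(st1, st2)
})

test_that("rebuilds are deterministic regardless of input order", {
  corpus <- smallCorpus(n = 5, planted = 1, seed = 73)
  structs <- lapply(corpus$files, loadStructure)
  a <- buildIndex(structs, tempfile("a"))
  b <- buildIndex(rev(structs), tempfile("b"))
  binsA <- list.files(file.path(indexPath(a), "bins"), recursive = TRUE)
  binsB <- list.files(file.path(indexPath(b), "bins"), recursive = TRUE)
  expect_setequal(binsA, binsB)
  for (f in binsA)
    expect_identical(readRDS(file.path(indexPath(a), "bins", f)),
                     readRDS(file.path(indexPath(b), "bins", f)))
  expect_equal(indexStats(a), indexStats(b))
})

test_that("tolerance-expanded lookups agree with a brute-force scan", {
  corpus <- smallCorpus(n = 5, planted = 2, seed = 19)
  structs <- lapply(corpus$files, loadStructure)
  idx <- buildIndex(structs, tempfile("idx"))
  ref <- parseKey(renderKey(binDescriptor("H", "S",
    pairGeometry(syntheticTriadMotif()[[1]], syntheticTriadMotif()[[3]]))))
  for (tol in 0:1) {
    got <- do.call(rbind, lapply(neighborKeys(ref, tol), function(k)
      lookupBin(idx, k)))
    gotSet <- sort(paste(got$sid,
                         renderLocator(got$chain1, got$operator1, got$seq1),
                         renderLocator(got$chain2, got$operator2, got$seq2)))
    want <- character(0)
    for (s in structs) {
      op <- oraclePairs(s)
      res <- residueTable(s)
      for (r in seq_len(nrow(op))) {
        if (op$typePair[r] != "HS") next
        if (abs(op$db[r] - ref$dbBin) > tol || abs(op$ds[r] - ref$dsBin) > tol ||
            abs(op$theta[r] - ref$thetaBin) > tol) next
        i <- op$i[r]; j <- op$j[r]
        want <- c(want, paste(structureId(s),
          renderLocator(res$chain[i], res$operator[i], res$seq[i]),
          renderLocator(res$chain[j], res$operator[j], res$seq[j])))
      }
    }
    expect_identical(gotSet, sort(want))
  }
})

test_that("the coordinate store round-trips at 0.1 A and reads selectively", {
  s <- generateStructure(60, seed = 9, structureId = "STORE")
  idx <- buildIndex(list(s), tempfile("idx"))
  res <- residueTable(s)
  pick <- c(5L, 40L, 17L)
  locs <- lapply(pick, function(i) c(res$chain[i], res$operator[i], res$seq[i]))
  got <- fetchResidues(idx, "STORE", locs)
  expect_length(got, 3L)
  for (k in seq_along(pick)) {
    i <- pick[k]
    expect_equal(got[[k]]$code, res$code[i])
    # stored coordinates are the full-precision ones rounded to 1 decimal
    orig <- s@atoms[s@atoms$res == i, ]
    expect_identical(rownames(got[[k]]$atoms), orig$name)
    expect_equal(got[[k]]$atoms[, "x"], round(orig$x, 1),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(got[[k]]$backbone,
                 round(c(res$bx[i], res$by[i], res$bz[i]), 1))
  }
  # selective access: three residues read far less than the whole file
  expect_lt(attr(got, "bytes_read"),
            file.size(file.path(indexPath(idx), "store", "STORE.dat")) / 5)
  expect_identical(fetchResidues(idx, "STORE", list()), structure(list(), bytes_read = 0))
  expect_error(fetchResidues(idx, "STORE", list(c("Z", "1", 1))), "missing residue")
  expect_error(fetchResidues(idx, "NOPE", list(c("A", "1", 1))), "missing structure")
})

test_that("corrupted bin files and manifests are detected", {
  s <- motifAsStructure(syntheticTriadMotif(), "C")
  idx <- buildIndex(list(s), tempfile("idx"))
  f <- list.files(file.path(indexPath(idx), "bins"), recursive = TRUE,
                  full.names = TRUE)[1]
  writeLines("garbage", f)
  key <- as.integer(sub("\\.rds$", "", basename(f)))
  expect_error(lookupBin(idx, key), "integrity error")
  mf <- file.path(indexPath(idx), "manifest.json")
  m <- jsonlite::read_json(mf)
  m$total_pairs <- 999
  jsonlite::write_json(m, mf, auto_unbox = TRUE)
  expect_error(openIndex(indexPath(idx)), "checksum")
})
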
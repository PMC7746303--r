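# Command-line interface: exit codes, outputs, reproducibility.

cliQuietly <- function(expr) {
  # CLI chatter goes to stderr via message(); keep test output clean
  suppressMessages(force(expr))
}

writeTriadQueryFile <- function(dir) {
  ref <- file.path(dir, "reference.cif")
  writeMmcif(motifAsStructure(syntheticTriadMotif(), "REF"), ref)
  qf <- file.path(dir, "query.json")
  jsonlite::write_json(list(reference = "reference.cif",
                            selectors = c("A-1", "A-2", "A-3")),
                       qf, auto_unbox = TRUE)
  qf
}

test_that("index build / update mirror the programmatic API", {
  wd <- tempfile("cli"); dir.create(wd)
  corpusA <- makeBenchmarkCorpus(4, 1, sigma = 0, seed = 3,
                                 dir = file.path(wd, "corpusA"),
                                 nResidues = c(20L, 30L))
  corpusB <- makeBenchmarkCorpus(3, 1, sigma = 0, seed = 4,
                                 dir = file.path(wd, "corpusB"),
                                 nResidues = c(20L, 30L))
  # ids must differ across the two corpora for the union
  for (f in corpusB$files) {
    txt <- readLines(f)
    file.remove(f)
    writeLines(gsub("SYN000", "SYNB00", txt),
               file.path(dirname(f), sub("SYN000", "SYNB00", basename(f))))
  }
  idxDir <- file.path(wd, "idx")
  expect_equal(cliQuietly(cliIndex(c("build", "--input", corpusA$dir,
                                     "--out", idxDir))), 0L)
  m <- indexManifest(openIndex(idxDir))
  expect_length(m$indexed, 4L)
  expect_equal(cliQuietly(cliIndex(c("update", "--input", corpusB$dir,
                                     "--out", idxDir))), 0L)
  # union rebuild gives identical stats
  unionDir <- file.path(wd, "union")
  all <- c(corpusA$files, list.files(corpusB$dir, pattern = "SYNB.*cif$",
                                     full.names = TRUE))
  expect_equal(cliQuietly(cliIndex(c("build", "--input", wd, "--out",
                                     file.path(wd, "nope")))), 0L)
  unlink(file.path(wd, "nope"), recursive = TRUE)  # wd has no cif files
  idx2 <- buildIndex(all, unionDir)
  expect_equal(indexStats(openIndex(idxDir)), indexStats(idx2))
  # colliding id without --replace fails with a data error
  expect_equal(cliQuietly(cliIndex(c("update", "--input", corpusA$dir,
                                     "--out", idxDir))), 1L)
  expect_equal(cliQuietly(cliIndex(c("update", "--input", corpusA$dir,
                                     "--out", idxDir, "--replace"))), 0L)
  # usage errors are distinct from data errors
  expect_equal(cliQuietly(cliIndex(c("frobnicate"))), 2L)
  expect_equal(cliQuietly(strucmotifCLI(character(0))), 2L)
  expect_equal(cliQuietly(strucmotifCLI("nonsense")), 2L)
})

test_that("search writes deterministic hit tables and a run report", {
  wd <- tempfile("cli"); dir.create(wd)
  corpus <- makeBenchmarkCorpus(6, 3, sigma = 0.1, seed = 5,
                                dir = file.path(wd, "corpus"),
                                nResidues = c(20L, 40L))
  idxDir <- file.path(wd, "idx")
  cliQuietly(cliIndex(c("build", "--input", corpus$dir, "--out", idxDir)))
  qf <- writeTriadQueryFile(wd)

  out1 <- file.path(wd, "run1")
  expect_equal(cliQuietly(cliSearch(c("--index", idxDir, "--query", qf,
                                      "--rmsd-cutoff", "1.0",
                                      "--out", out1))), 0L)
  hits <- read.csv(paste0(out1, "_hits.csv"), stringsAsFactors = FALSE)
  expect_true(all(hits$rmsd <= 1.0))
  expect_true(all(c("structure_id", "assignment", "rmsd", "atom_count",
                    "atom_mode", "r11", "tz") %in% names(hits)))
  report <- jsonlite::read_json(paste0(out1, "_report.json"))
  expect_equal(report$hits, nrow(hits))
  expect_equal(report$config$atom_mode, "sidechain")
  expect_equal(report$config$tolerance, 1L)
  expect_true(!is.null(report$structures$rejected))

  # identical inputs -> byte-identical hit tables
  out2 <- file.path(wd, "run2")
  cliQuietly(cliSearch(c("--index", idxDir, "--query", qf,
                         "--rmsd-cutoff", "1.0", "--out", out2)))
  expect_identical(readLines(paste0(out1, "_hits.csv")),
                   readLines(paste0(out2, "_hits.csv")))

  # tolerance monotonicity through the CLI
  hitsAt <- function(tol) {
    out <- file.path(wd, paste0("tol", tol))
    cliQuietly(cliSearch(c("--index", idxDir, "--query", qf,
                           "--tolerance", tol, "--out", out)))
    read.csv(paste0(out, "_hits.csv"), stringsAsFactors = FALSE)$assignment
  }
  expect_true(all(hitsAt(0) %in% hitsAt(1)))

  # jsonl output
  outj <- file.path(wd, "runj")
  cliQuietly(cliSearch(c("--index", idxDir, "--query", qf, "--format",
                         "jsonl", "--out", outj)))
  jl <- readLines(paste0(outj, "_hits.jsonl"))
  expect_equal(length(jl), nrow(read.csv(paste0(out2, "_hits.csv"))))

  # bad query selectors give a nonzero exit naming the selector
  badq <- file.path(wd, "bad.json")
  jsonlite::write_json(list(reference = file.path(wd, "reference.cif"),
                            selectors = c("A-1", "A-99")),
                       badq, auto_unbox = TRUE)
  expect_equal(cliQuietly(cliSearch(c("--index", idxDir, "--query", badq,
                                      "--out", file.path(wd, "bad")))), 1L)
  expect_equal(cliQuietly(cliSearch(c("--index", file.path(wd, "noidx"),
                                      "--query", qf,
                                      "--out", file.path(wd, "x")))), 1L)
  expect_equal(cliQuietly(cliSearch(character(0))), 2L)
})

test_that("stats emits the descriptor table and synth generates corpora", {
  wd <- tempfile("cli"); dir.create(wd)
  expect_equal(cliQuietly(cliSynth(c("corpus", "--n-structures", "4",
                                     "--n-planted", "2", "--sigma", "0",
                                     "--seed", "9", "--out",
                                     file.path(wd, "corpus")))), 0L)
  expect_length(list.files(file.path(wd, "corpus"), pattern = "cif$"), 4L)
  expect_true(file.exists(file.path(wd, "corpus", "truth.csv")))

  idxDir <- file.path(wd, "idx")
  cliQuietly(cliIndex(c("build", "--input", file.path(wd, "corpus"),
                        "--out", idxDir)))
  statsCsv <- file.path(wd, "stats.csv")
  expect_equal(cliQuietly(cliStats(c("--index", idxDir, "--top", "5",
                                     "--out", statsCsv))), 0L)
  st <- read.csv(statsCsv, stringsAsFactors = FALSE)
  expect_lte(nrow(st), 5L)
  expect_named(st, c("descriptor", "structures", "occurrences"))
  # N larger than the bin count emits everything, totals match manifest
  cliQuietly(cliStats(c("--index", idxDir, "--top", "999999",
                        "--out", statsCsv)))
  st <- read.csv(statsCsv, stringsAsFactors = FALSE)
  m <- indexManifest(openIndex(idxDir))
  expect_equal(nrow(st), m$bin_count)
  expect_equal(sum(st$occurrences), m$total_pairs)
  expect_equal(cliQuietly(cliStats(c("--index", file.path(wd, "missing")))), 1L)
  expect_equal(cliQuietly(cliSynth(c("corpus"))), 2L)
})
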
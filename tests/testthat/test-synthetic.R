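test_that("generator respects the length budget and is seed-deterministic", {
  for (seed in 1:5) {
    cfg <- stConfig(seed = seed, spLen = 19 + seed, nRepeats = 2 + seed,
                    repeatLen = 22 + (seed %% 5))
    rec <- generateST(cfg)
    expected <- cfg$spLen + cfg$ntermLen +
      (cfg$nRepeats - 1) * cfg$repeatLen + cfg$truncatedLen
    expect_identical(nchar(rec$residues), as.integer(expected))
    expect_identical(generateST(cfg)$residues, rec$residues)
  }
  expect_error(stConfig(spLen = 30))
  expect_error(stConfig(nRepeats = 1))
  expect_error(stConfig(truncatedLen = 25, repeatLen = 25))
})

test_that("re-annotating noise-free output reproduces the ground truth", {
  for (seed in c(1, 17, 33)) {
    cfg <- stConfig(seed = seed, stType = c("I", "IIa", "III")[seed %% 3 + 1])
    rec <- generateST(cfg)
    ann <- annotateSequence(rec$residues, id = rec$id)
    u <- repeatUnits(ann)
    expect_identical(u$start, rec$truth$units$start)
    expect_identical(u$end, rec$truth$units$end)
    expect_identical(u$status, rec$truth$units$status)
    expect_identical(u$x4, rec$truth$units$x4)
    expect_identical(ann@cleavageAfter, rec$truth$cleavageAfter)
    expect_identical(ann@mature$ywPosition, rec$truth$ywPositionMature)
    expect_identical(ann@mature$cysPosition, rec$truth$cysPositionMature)
    expect_identical(stType(ann), rec$truth$stType)
    expect_identical(completeness(ann), rec$truth$completeness)
  }
})

test_that("type IIa units carry a sequon at unit position 7 in every repeat", {
  rec <- generateST(stConfig(seed = 44, stType = "IIa", nRepeats = 10))
  u <- repeatUnits(annotateSequence(rec$residues))
  for (s in u$seq) {
    expect_identical(substr(s, 7, 7), "N")
    expect_identical(nglycSites(substr(s, 7, 11))$position, 1L)
  }
})

test_that("fragment modes strip the designed termini", {
  internal <- generateST(stConfig(seed = 50, fragmentMode = "internal"))
  expect_false(startsWith(internal$residues, "M"))
  n <- nchar(internal$residues)
  last4 <- substr(internal$residues, n - 3, n)
  expect_false(substr(last4, 1, 1) == "Y" || substr(last4, 2, 2) == "Y")
  expect_identical(internal$truth$completeness, "internal")

  nOnly <- generateST(stConfig(seed = 50, fragmentMode = "n_only"))
  expect_true(startsWith(nOnly$residues, "M"))
  expect_identical(nOnly$truth$completeness, "n_complete")
})

test_that("decoys of every kind carry no ST signature", {
  kinds <- c("prp", "hrgp", "grp", "agp", "shuffled_st")
  for (k in kinds) {
    d <- generateDecoy(k, seed = 7)
    expect_false(isSTProtein(d$residues))
    expect_identical(d$residues, generateDecoy(k, seed = 7)$residues)
  }
  g <- generateDecoy("grp", seed = 1)
  expect_gt(mean(strsplit(g$residues, "")[[1]] == "G"), 0.4)
  # shuffle preserves composition
  s <- generateDecoy("shuffled_st", seed = 3)
  src <- generateST(stConfig(seed = 3))
  expect_identical(sort(strsplit(s$residues, "")[[1]]),
                   sort(strsplit(src$residues, "")[[1]]))
  expect_error(generateDecoy("unknown"))
})

test_that("family generation is reproducible and labels clades", {
  fam <- generateFamily(nSpecies = 4, seqsPerSpecies = 2,
                        cladeTemplates = c("I", "IIa"), seed = 12,
                        withinNoise = 0.02)
  expect_identical(length(fam$seqs), 8L)
  expect_identical(nrow(fam$truth), 8L)
  expect_setequal(unique(fam$truth$clade), c(1L, 2L))
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeFasta(fam$seqs, f1)
  fam2 <- generateFamily(nSpecies = 4, seqsPerSpecies = 2,
                         cladeTemplates = c("I", "IIa"), seed = 12,
                         withinNoise = 0.02)
  writeFasta(fam2$seqs, f2)
  expect_identical(readLines(f1), readLines(f2))
  # species codes are 3 letters and each species keeps its clade's type
  expect_true(all(grepl("^[A-Z][a-z]{2}ST[0-9]+$", fam$truth$id)))
})

test_that("the synthetic curated stand-in matches its designed marginals", {
  cur <- generateCuratedSet(seed = 2012)
  expect_identical(length(cur$seqs), 136L)
  expect_identical(sum(cur$truth$completeness == "full"), 72L)
  expect_identical(sum(cur$truth$completeness == "n_complete"), 38L)
  expect_identical(sum(cur$truth$completeness == "c_complete"), 7L)
  expect_identical(sum(cur$truth$completeness == "internal"), 19L)
  full <- cur$truth[cur$truth$completeness == "full", ]
  expect_identical(min(full$lengthFull), 103L)
  expect_identical(max(full$lengthFull), 493L)
  expect_identical(range(full$nRepeats), c(2L, 17L))
  expect_identical(sum(cur$truth$stType == "I"), 29L)
  expect_identical(sum(cur$truth$stType == "IIa"), 75L)
})
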
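test_that("scanMotif finds (D/E)FEPRP-X4-Y anchors and requires the Tyr", {
  expect_identical(scanMotif("RKDFEPRPNVSAYAAAA"), 3L)
  expect_identical(scanMotif("EFEPRPKVTAY"), 1L)      # Glu variant
  expect_identical(scanMotif("DFEPRPNVSA"), integer(0))  # no Tyr at 11
  expect_identical(scanMotif("DFEPRPNVSAW"), integer(0))
  expect_identical(scanMotif(""), integer(0))
  # two tandem anchors
  s <- paste0(REF_UNIT, REF_UNIT)
  expect_identical(scanMotif(s), c(1L, 26L))
  # one hexamer mismatch only admitted when requested; Tyr never relaxed
  m <- "DFAPRPNVSAY"
  expect_identical(scanMotif(m), integer(0))
  expect_identical(scanMotif(m, maxHexamerMismatch = 1L), 1L)
  expect_identical(scanMotif("DFAPRPNVSAW", maxHexamerMismatch = 1L),
                   integer(0))
})

test_that("segmentation partitions the repeat span and flags the truncated unit", {
  # three anchors on a 63-aa string: units 25, 25, 13 (last truncated)
  s <- paste0(substr(REF_UNIT, 1, 25), substr(REF_UNIT, 1, 25),
              substr(REF_UNIT, 1, 13))
  region <- segmentRepeats(s)
  u <- repeatUnits(region)
  expect_identical(u$length, c(25L, 25L, 13L))
  expect_identical(u$status,
                   c("canonical", "canonical", "truncated_terminal"))
  expect_identical(modalLength(region), 25L)
  # exact partition: first anchor to C-terminus, no gaps or overlaps
  expect_identical(u$start[1], 1L)
  expect_identical(u$end[nrow(u)], nchar(s))
  expect_identical(u$start[-1], u$end[-nrow(u)] + 1L)

  # single anchor with 13 residues to the C-terminus: one truncated unit
  one <- substr(REF_UNIT, 1, 13)
  r1 <- segmentRepeats(one)
  expect_identical(nrow(repeatUnits(r1)), 1L)
  expect_identical(repeatUnits(r1)$status, "truncated_terminal")

  expect_error(segmentRepeats("MKKKKKK"), "not an ST signature")
})

test_that("length patterns distinguish uniform, alternating and heterogeneous", {
  mk <- function(lens) {
    units <- vapply(lens, function(L)
      paste0("DFEPRPNVSAY", strrep("K", L - 11L)), character(1))
    paste(c(units, substr(REF_UNIT, 1, 13)), collapse = "")
  }
  expect_identical(segmentRepeats(mk(c(25, 25, 25)))@lengthPattern,
                   "uniform")
  expect_identical(segmentRepeats(mk(c(25, 26, 25, 26)))@lengthPattern,
                   "alternating")
  expect_identical(segmentRepeats(mk(c(25, 26, 26, 25)))@lengthPattern,
                   "heterogeneous")
})

test_that("fuzzy pre-scan adds imperfect leading units", {
  lead <- "DFAPRPKVTAYKAKKDFKDNDADSK"  # 1 hexamer mismatch, Tyr intact
  s <- paste0(lead, strrep(REF_UNIT, 2), substr(REF_UNIT, 1, 13))
  region <- segmentRepeats(s)
  u <- repeatUnits(region)
  expect_identical(u$status[1], "imperfect_leading")
  expect_identical(u$start[1], 1L)
  expect_identical(sum(u$status == "canonical"), 2L)
  # and without the fuzzy pre-scan the leading unit is absent
  u2 <- repeatUnits(segmentRepeats(s, fuzzyLeading = FALSE))
  expect_identical(u2$start[1], 26L)
})

test_that("consensus emits majority residues and X below threshold", {
  s <- paste0(strrep(REF_UNIT, 4), substr(REF_UNIT, 1, 13))
  region <- segmentRepeats(s)
  expect_identical(deriveConsensus(region), REF_UNIT)

  # 50/50 column at threshold 0.5 resolves to the first unit's residue
  a <- "DFEPRPNVSAYDNDADKSKAKKDFK"
  b <- "DFEPRPSVSAYDNDADKSKAKKDFK"  # differs at position 7 (N vs S)
  region2 <- segmentRepeats(paste0(a, b, substr(a, 1, 13)))
  cons <- deriveConsensus(region2)
  expect_identical(substr(cons, 7, 7), "N")
  # below threshold the column becomes X
  expect_identical(substr(deriveConsensus(region2, threshold = 0.6), 7, 7),
                   "X")
  expect_error(deriveConsensus(segmentRepeats(substr(a, 1, 25))),
               ">= 2")
})

test_that("consensus on a noisy type-IIa family keeps the anchored motif", {
  rec <- generateST(stConfig(seed = 42, nRepeats = 8, stType = "IIa",
                             substitutionRate = 0.05))
  region <- repeatRegion(annotateSequence(rec$residues))
  cons <- deriveConsensus(region)
  expect_identical(substr(cons, 1, 6), "DFEPRP")
  expect_identical(substr(cons, 11, 11), "Y")
})

test_that("psimScore equals the brute-force oracle on toy unit sets", {
  # frozen worked examples
  two <- c(REF_UNIT, REF_UNIT)
  mk <- function(seqs) {
    segmentRepeats(paste(seqs, collapse = ""))
  }
  expect_identical(psimScore(mk(two)), 1)
  oneDiff <- c(REF_UNIT, sub("NVSA", "NVKA", REF_UNIT))
  expect_identical(psimScore(mk(oneDiff)), 0.98)  # 49/50, oracle-derived
  expect_identical(oraclePsim(oneDiff), 0.98)

  # randomized 2-4 unit sets, truncated terminal included
  set.seed(99)
  for (i in 1:25) {
    nU <- sample(2:4, 1)
    units <- vapply(seq_len(nU), function(k) {
      u <- strsplit(REF_UNIT, "")[[1]]
      flip <- sample(12:25, sample(0:6, 1))
      for (p in flip) u[p] <- sample(setdiff(LETTERS, c(u[p], "Y")), 1)
      paste(u, collapse = "")
    }, character(1))
    units[nU] <- substr(units[nU], 1, sample(c(13, 25), 1))
    region <- mk(units)
    expect_identical(repeatUnits(region)$seq, unname(units))
    expect_equal(psimScore(region), oraclePsim(units), tolerance = 1e-12)
  }
})

test_that("psim is 1 iff unanimous and order-invariant for distinct profiles", {
  s1 <- c(REF_UNIT, sub("DND", "DSD", REF_UNIT), REF_UNIT)
  r1 <- segmentRepeats(paste(s1, collapse = ""))
  r2 <- segmentRepeats(paste(s1[c(3, 1, 2)], collapse = ""))
  expect_equal(psimScore(r1), psimScore(r2))
  expect_lt(psimScore(r1), 1)
  # units sharing no majority beyond the anchor score below 0.7
  u1 <- paste0("DFEPRPNVSAY", strrep("A", 14))
  u2 <- paste0("DFEPRPSKTVY", strrep("G", 14))
  low <- segmentRepeats(paste0(u1, u2))
  expect_lt(psimScore(low), 0.7)
  expect_equal(psimScore(low), oraclePsim(c(u1, u2)))
})

test_that("DUF-like domain proxy counts 3-unit windows", {
  mk <- function(n) {
    segmentRepeats(paste0(strrep(REF_UNIT, n - 1),
                          substr(REF_UNIT, 1, 13)))
  }
  expect_identical(countDufLikeDomains(mk(3)),
                   c(complete = 1L, truncated = 0L))
  expect_identical(countDufLikeDomains(mk(2)),
                   c(complete = 0L, truncated = 1L))
  expect_identical(countDufLikeDomains(mk(7)),
                   c(complete = 2L, truncated = 1L))
  expect_identical(countDufLikeDomains(mk(6)),
                   c(complete = 2L, truncated = 0L))
})
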
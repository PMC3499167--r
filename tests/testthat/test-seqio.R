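test_that("readFasta parses headers, concatenates lines and validates ids", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">CarST1 chickpea seed", "RKMDFE", ">a", "MD", "FE"), f)
  seqs <- readFasta(f)
  expect_identical(unname(seqs["CarST1"]), "RKMDFE")
  expect_identical(unname(seqs["a"]), "MDFE")
  expect_identical(unname(attr(seqs, "description")["CarST1"]),
                   "chickpea seed")

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "MD", ">a", "FE"), dup)
  expect_error(readFasta(dup), "duplicate.*a")

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(readFasta(empty), "empty")

  starred <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "MDFE*"), starred)
  expect_warning(s <- readFasta(starred), "\\*")
  expect_identical(unname(s["a"]), "MDFE")
})

test_that("writeFasta wraps lines and round-trips with readFasta", {
  f <- withr::local_tempfile(fileext = ".fa")
  long <- paste(rep("A", 70), collapse = "")
  writeFasta(c(one = long), f)
  lines <- readLines(f)
  expect_length(lines, 3L)
  expect_identical(nchar(lines[2:3]), c(60L, 10L))

  set.seed(11)
  seqs <- setNames(
    vapply(1:5, function(i)
      paste(sample(c("A", "R", "N", "D", "K"), 37 * i, TRUE),
            collapse = ""), character(1)),
    paste0("s", 1:5))
  writeFasta(seqs, f)
  back <- readFasta(f)
  expect_identical(as.vector(back), as.vector(seqs))
  expect_identical(names(back), names(seqs))
  # write(read(write(x))) is byte-identical
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeFasta(back, f2)
  expect_identical(readLines(f2), readLines(f))

  writeFasta(character(0), f2)
  expect_identical(readLines(f2), character(0))
})

test_that("six-frame translation follows the standard code", {
  expect_identical(unname(sixFrameTranslate("ATGGATTTT")[1]), "MDF")
  expect_identical(unname(sixFrameTranslate("ATGTAA")[1]), "M*")
  # hand-translated reverse complement of AAACAT is ATGTTT -> MF
  expect_identical(unname(sixFrameTranslate("AAACAT")[4]), "MF")
  # trailing partial codons dropped; N -> X
  expect_identical(unname(sixFrameTranslate("ATGNATTA")[1]), "MX")
  expect_error(sixFrameTranslate("MDFE"), "nucleotide")
})

test_that("translating the reverse complement swaps +/- frames exactly", {
  set.seed(3)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 30 + i, TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    fr <- sixFrameTranslate(s)
    fr2 <- sixFrameTranslate(rc)
    expect_identical(unname(fr[1:3]), unname(fr2[4:6]))
    expect_identical(unname(fr[4:6]), unname(fr2[1:3]))
  }
})

test_that("feature tables carry 1-based inclusive coordinates", {
  rec <- generateST(stConfig(seed = 5))
  ann <- annotateSequence(rec$residues, id = rec$id)
  gff <- withr::local_tempfile(fileext = ".gff3")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  feats <- writeFeatureTable(ann, gff, fmt = "gff3")
  writeFeatureTable(ann, tsv, fmt = "tsv")

  lines <- readLines(gff)
  expect_identical(lines[1], "##gff-version 3")
  body <- read.delim(text = lines[-1], header = FALSE)
  expect_true(all(body$V2 == "repeatst"))
  # repeat rows match the segmentation exactly
  reps <- body[body$V3 %in% c("repeat", "truncated_repeat"), ]
  u <- repeatUnits(ann)
  expect_identical(reps$V4, u$start)
  expect_identical(reps$V5, u$end)
  # glyco sites span exactly 3 residues
  gl <- body[body$V3 == "glyco_site", ]
  expect_true(all(gl$V5 - gl$V4 == 2L))

  tab <- read.delim(tsv)
  expect_identical(nrow(tab), nrow(feats))
  expect_true(all(tab$start >= 1 & tab$start <= tab$end))

  # rejected-only input yields a header-only file
  writeFeatureTable(annotateSequence("MKKKKKKKKKK", id = "x"), gff)
  expect_identical(readLines(gff), "##gff-version 3")
})
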
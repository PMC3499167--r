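test_that("pairwise identity distance behaves on worked examples", {
  expect_identical(pairwiseDistance("AAAA", "AAAA"), 0)
  expect_equal(pairwiseDistance("AAAA", "AATA"), 0.25)
  # disjoint alphabets: no identities
  expect_gte(pairwiseDistance("AAAA", "KKKK"), 0.99)
  expect_error(pairwiseDistance("", "AA"), "empty")
  # symmetry and identity axioms over random pairs
  set.seed(21)
  for (i in 1:5) {
    a <- paste(sample(c("A", "K", "D", "F", "S"), 20, TRUE), collapse = "")
    b <- paste(sample(c("A", "K", "D", "F", "S"), 17, TRUE), collapse = "")
    expect_equal(pairwiseDistance(a, b), pairwiseDistance(b, a))
    expect_identical(pairwiseDistance(a, a), 0)
  }
})

test_that("njTree validates input and solves the 3-taxon closed form", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.4,
                0.5, 0.4, 0), 3, dimnames = list(letters[1:3],
                                                 letters[1:3]))
  tr <- njTree(d)
  expect_setequal(tr$tip.label, letters[1:3])
  # three-point formulas: x_a = (d_ab + d_ac - d_bc) / 2, etc.
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl["a"]), (0.3 + 0.5 - 0.4) / 2)
  expect_equal(unname(bl["b"]), (0.3 + 0.4 - 0.5) / 2)
  expect_equal(unname(bl["c"]), (0.5 + 0.4 - 0.3) / 2)

  bad <- d; bad[1, 2] <- 0.9
  expect_error(njTree(bad), "symmetric")
  expect_error(njTree(d[1:2, 1:2]), ">= 3")
})

test_that("NJ recovers the generating topology of additive 4-taxon matrices", {
  # exhaustive check against the four-point-condition oracle over random
  # additive trees of each of the three quartet topologies
  set.seed(22)
  taxa <- c("a", "b", "c", "d")
  for (rep in 1:30) {
    e <- runif(5, 0.05, 1)  # 4 pendant edges + internal edge
    topo <- sample(1:3, 1)
    pairs <- list(c(1, 2), c(1, 3), c(1, 4))[[topo]]
    # build the additive matrix for topology pairing taxon 1 with 'mate'
    mate <- pairs[2]
    others <- setdiff(2:4, mate)
    d <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
    for (i in 1:3) for (j in (i + 1):4) {
      samePair <- (i == 1 && j == mate) ||
        (i == others[1] && j == others[2])
      d[i, j] <- d[j, i] <- e[i] + e[j] + if (samePair) 0 else e[5]
    }
    expect_identical(oracleQuartet(d), topo)  # oracle self-consistency
    tr <- njTree(d)
    expect_true(hasSplit(tr, c(taxa[1], taxa[mate])))
  }
})

test_that("identical sequences form a zero-length cherry", {
  seqs <- c(x = "DFEPRPNVSAY", y = "DFEPRPNVSAY", z = "SKTVSKTVSKT")
  d <- distanceMatrix(seqs)
  expect_identical(d["x", "y"], 0)
  tr <- njTree(d)
  bl <- tr$edge.length[match(match(c("x", "y"), tr$tip.label),
                             tr$edge[, 2])]
  expect_true(all(abs(bl) < 1e-12))
})

test_that("bootstrap supports are reproducible and sensible", {
  fam <- generateFamily(nSpecies = 6, seqsPerSpecies = 1,
                        cladeTemplates = c("I", "IIa"), seed = 3,
                        withinNoise = 0.02)
  anns <- lapply(names(fam$seqs), function(id)
    annotateSequence(fam$seqs[[id]], id = id))
  mat <- repeatAlignment(anns)
  expect_identical(sort(rownames(mat)), sort(fam$truth$id))

  t1 <- bootstrapSupport(mat, nReplicates = 100, seed = 9)
  t2 <- bootstrapSupport(mat, nReplicates = 100, seed = 9)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  # leaves group by clade template: the between-clade split is present
  # and strongly supported
  cladeA <- fam$truth$id[fam$truth$clade == 1]
  expect_true(hasSplit(t1, cladeA))
  expect_true(any(as.numeric(t1$node.label) > 95, na.rm = TRUE))

  expect_error(bootstrapSupport(mat, nReplicates = 0), ">= 1")
  # single replicate: supports are 0 or 100
  t3 <- bootstrapSupport(mat, nReplicates = 1, seed = 2)
  sup <- suppressWarnings(as.numeric(t3$node.label))
  expect_true(all(sup %in% c(0, 100) | is.na(sup)))
})

test_that("family clades are monophyletic at zero noise", {
  fam <- generateFamily(nSpecies = 8, seqsPerSpecies = 1,
                        cladeTemplates = c("I", "IIa"), seed = 5,
                        withinNoise = 0)
  d <- distanceMatrix(fam$seqs)
  tr <- njTree(d)
  for (cl in unique(fam$truth$clade)) {
    tips <- fam$truth$id[fam$truth$clade == cl]
    expect_true(hasSplit(tr, tips))
  }
})

test_that("PHYLIP distance matrix output is readable", {
  d <- distanceMatrix(c(a = "AAAA", b = "AATA", c = "KKKK"))
  f <- withr::local_tempfile(fileext = ".dist")
  writePhylip(d, f)
  lines <- readLines(f)
  expect_identical(as.integer(trimws(lines[1])), 3L)
  expect_length(lines, 4L)
})
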
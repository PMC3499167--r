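# Independent oracles used by the test suite. Each reimplements the checked
# quantity by a different route (explicit loops, closed forms, exhaustive
# enumeration) and is kept free of package internals.

# brute-force Psim: per column, find the majority residue by scanning
# candidates in unit order (strictly-greater replacement = first-seen
# tie-break), then count matches over all unit positions
oraclePsim <- function(unitSeqs) {
  L <- max(nchar(unitSeqs))
  total <- 0
  matches <- 0
  for (j in seq_len(L)) {
    col <- character(0)
    for (u in unitSeqs) {
      if (nchar(u) >= j) col <- c(col, substr(u, j, j))
    }
    best <- NA_character_
    bestN <- 0L
    for (r in col) {
      nr <- sum(col == r)
      if (nr > bestN) {
        best <- r
        bestN <- nr
      }
    }
    total <- total + length(col)
    matches <- matches + sum(col == best)
  }
  matches / total
}

# entropy-based information content of one column of residues
oracleBits <- function(column) {
  f <- table(column) / length(column)
  log2(20) - (-sum(f * log2(f)))
}

# four-point condition: which of the three 4-taxon topologies an additive
# matrix supports (1 = ab|cd, 2 = ac|bd, 3 = ad|bc)
oracleQuartet <- function(d) {
  sums <- c(d[1, 2] + d[3, 4], d[1, 3] + d[2, 4], d[1, 4] + d[2, 3])
  which.min(sums)
}

# the bipartition {t1, t2} | rest present in an unrooted tree?
hasSplit <- function(tree, pair) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  for (p in parts) {
    side <- sort(labs[p])
    other <- sort(setdiff(labs, side))
    if (identical(side, sort(pair)) || identical(other, sort(pair)))
      return(TRUE)
  }
  FALSE
}

# net charge at a given pH under the EMBOSS pKa set (independent recompute
# used to verify the bisection residual)
oracleNetCharge <- function(residues, pH) {
  ch <- strsplit(toupper(residues), "")[[1]]
  pka <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
           H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
  pos <- 1 / (1 + 10^(pH - pka["Nterm"]))
  for (a in c("H", "K", "R"))
    pos <- pos + sum(ch == a) / (1 + 10^(pH - pka[a]))
  neg <- 1 / (1 + 10^(pka["Cterm"] - pH))
  for (a in c("C", "D", "E", "Y"))
    neg <- neg + sum(ch == a) / (1 + 10^(pka[a] - pH))
  unname(pos - neg)
}

# a canonical 25-aa repeat used by several tests
REF_UNIT <- "DFEPRPNVSAYDNDADKSKAKKDFK"
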
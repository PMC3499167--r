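# residue pools used by the generator. The mature protein of the emulated
# family is highly hydrophilic; Cys, Trp, Tyr, Met and Arg are excluded
# from filler so that the designated feature positions (single Cys, single
# Trp, anchor Tyr, initial Met, mature Arg) stay unique by construction.
NTERM_FILLER <- c("A", "D", "E", "G", "K", "N", "P", "Q", "S", "T", "H")
# acidic-leaning filler: the mature protein is acidic overall, with the
# acidic fraction exceeding the basic one
NTERM_FILLER_PROB <- c(0.1, 0.18, 0.14, 0.08, 0.02, 0.14, 0.06, 0.06,
                       0.12, 0.08, 0.02)
TAIL_X <- c("D", "N", "E", "K", "S", "A")
TAIL_X_PROB <- c(0.35, 0.35, 0.15, 0.05, 0.05, 0.05)
SIGNAL_CORE <- c("L", "A", "V", "I", "F")
SUBST_POOL <- setdiff(AA20, c("C", "W"))

#' Generator configuration for synthetic ST precursors
#'
#' Defaults encode the canonical organization of the family: a 22-aa signal
#' peptide (the modal cleavage site), a 55-aa mature N-terminal region (the
#' most frequent length class), six repeats of 25 aa (the predominant
#' repeat length) of which the last is truncated to 13 aa, and no
#' substitution noise.
#'
#' @param seed RNG seed for the generate call.
#' @param spLen signal peptide length, in 19-28.
#' @param ntermLen mature N-terminal region length (>= 14).
#' @param nRepeats number of repeat units including the truncated terminal
#'   one, in 2-17.
#' @param repeatLen canonical repeat length, in 22-27.
#' @param stType "I", "IIa", "IIb", "III" or "mixed".
#' @param truncatedLen length of the terminal truncated repeat
#'   (< repeatLen; >= 11 so that it keeps its anchor and Tyr).
#' @param substitutionRate per-residue substitution probability.
#' @param protectAnchor protect hexapeptide and Tyr-11 positions from
#'   substitutions.
#' @param fragmentMode "full", "n_only", "c_only" or "internal".
#' @param unitTypes optional explicit per-unit type vector (length
#'   \code{nRepeats}), overriding \code{stType} per unit.
#' @return a validated list of class \code{stConfig}.
#' @export
stConfig <- function(seed = 1L, spLen = 22L, ntermLen = 55L,
                     nRepeats = 6L, repeatLen = 25L, stType = "IIa",
                     truncatedLen = 13L, substitutionRate = 0,
                     protectAnchor = TRUE, fragmentMode = "full",
                     unitTypes = NULL) {
  cfg <- list(seed = as.integer(seed), spLen = as.integer(spLen),
              ntermLen = as.integer(ntermLen),
              nRepeats = as.integer(nRepeats),
              repeatLen = as.integer(repeatLen), stType = stType,
              truncatedLen = as.integer(truncatedLen),
              substitutionRate = substitutionRate,
              protectAnchor = isTRUE(protectAnchor),
              fragmentMode = fragmentMode, unitTypes = unitTypes)
  stopifnot(cfg$spLen >= 19L, cfg$spLen <= 28L,
            cfg$ntermLen >= 14L,
            cfg$nRepeats >= 2L, cfg$nRepeats <= 17L,
            cfg$repeatLen >= 22L, cfg$repeatLen <= 27L,
            cfg$truncatedLen >= 11L, cfg$truncatedLen < cfg$repeatLen,
            cfg$substitutionRate >= 0, cfg$substitutionRate < 1,
            cfg$stType %in% c("I", "IIa", "IIb", "III", "mixed"),
            cfg$fragmentMode %in% c("full", "n_only", "c_only", "internal"))
  if (!is.null(unitTypes))
    stopifnot(length(unitTypes) == cfg$nRepeats,
              all(unitTypes %in% c("I", "IIa", "IIb", "III")))
  class(cfg) <- "stConfig"
  cfg
}

# X4 (unit positions 7-10) for one type
.x4For <- function(type) {
  switch(type,
    I   = c("S", sample(c("K", "V", "A", "G"), 1L), "T",
            sample(c("K", "V", "A", "G"), 1L)),
    IIa = c("N", sample(c("I", "V", "A"), 1L), "S",
            sample(c("I", "V", "A"), 1L)),
    IIb = c("N", sample(c("F", "S", "A", "L"), 1L),
            sample(c("F", "L"), 1L), sample(c("S", "A", "L"), 1L)),
    III = c(sample(c("D", "T"), 1L), sample(c("K", "V", "A"), 1L),
            sample(c("T", "S"), 1L), sample(c("K", "V", "A"), 1L)),
    stop("unknown type: ", type))
}

# repeat tail after the conserved Tyr: X6-7 region rich in D/N, then the
# K-rich block KXKKXFXK of the 25/26-aa consensus
.unitTail <- function(L) {
  nx <- L - 19L
  xreg <- if (nx > 0L) sample(TAIL_X, nx, replace = TRUE,
                              prob = TAIL_X_PROB) else character(0)
  kblock <- character(8L)
  for (i in c(1L, 3L, 4L, 8L)) {
    kblock[i] <- if (stats::runif(1) < 0.85) "K" else
      sample(c("N", "D", "E", "T"), 1L)
  }
  for (i in c(2L, 5L, 7L)) {
    kblock[i] <- sample(c("D", "N", "A", "S", "E", "T", "V", "K"), 1L,
                        prob = c(0.25, 0.25, 0.1, 0.1, 0.15, 0.05,
                                 0.05, 0.05))
  }
  kblock[6L] <- if (stats::runif(1) < 0.85) "F" else sample(c("L", "S"), 1L)
  c(xreg, kblock)
}

# one full canonical unit of length L and the given type
.buildUnit <- function(L, type, hexFirst = "D") {
  c(hexFirst, "F", "E", "P", "R", "P", .x4For(type), "Y", .unitTail(L))
}

#' Generate one ground-truthed synthetic ST precursor
#'
#' Builds a precursor with the canonical organization: Met + hydrophobic
#' core signal peptide; a hydrophilic mature N-terminal region starting
#' Arg-Lys with the Tyr-Trp dyad at mature positions 7-8 and a single Cys;
#' \code{nRepeats} tandem repeats built from the
#' (D/E)FEPRP + X4(type) + Tyr + consensus-style tail template, the final
#' unit truncated; optional substitution noise (anchor positions protected
#' by default). No Cys or Trp appears outside its designated position.
#' Deterministic for a given config.
#'
#' @param config an [stConfig()].
#' @param id sequence identifier.
#' @return list with \code{id}, \code{residues}, \code{description} and
#'   \code{truth}. For \code{fragmentMode = "full"}, \code{truth$units}
#'   carries exact repeat boundaries (precursor coordinates); fragment
#'   modes record the designed completeness and type.
#' @export
generateST <- function(config = stConfig(), id = "SynST1") {
  stopifnot(inherits(config, "stConfig"))
  set.seed(config$seed)
  sp <- c("M", sample(SIGNAL_CORE, config$spLen - 4L, replace = TRUE),
          sample(c("A", "S", "G"), 3L, replace = TRUE))

  nt <- sample(NTERM_FILLER, config$ntermLen, replace = TRUE,
               prob = NTERM_FILLER_PROB)
  nt[1L] <- "R"; nt[2L] <- "K"; nt[7L] <- "Y"; nt[8L] <- "W"
  cysPos <- min(config$ntermLen - 2L,
                max(10L, as.integer(round(0.55 * config$ntermLen))))
  nt[cysPos] <- "C"

  unitTypes <- config$unitTypes
  if (is.null(unitTypes)) {
    unitTypes <- if (config$stType == "mixed") {
      sample(c("I", "IIa", "III"), config$nRepeats, replace = TRUE)
    } else rep(config$stType, config$nRepeats)
  }
  units <- lapply(seq_len(config$nRepeats), function(k)
    .buildUnit(config$repeatLen, unitTypes[k]))
  units[[config$nRepeats]] <-
    units[[config$nRepeats]][seq_len(config$truncatedLen)]

  res <- c(sp, nt, unlist(units))
  n <- length(res)

  # truth: unit boundaries in precursor coordinates
  starts <- config$spLen + config$ntermLen +
    (seq_len(config$nRepeats) - 1L) * config$repeatLen + 1L
  ends <- c(starts[-1L] - 1L, n)
  status <- c(rep("canonical", config$nRepeats - 1L), "truncated_terminal")
  x4 <- vapply(units, function(u) paste(u[7:10], collapse = ""),
               character(1))

  # substitution noise
  if (config$substitutionRate > 0) {
    protected <- integer(0)
    if (config$protectAnchor) {
      protected <- unlist(lapply(starts, function(s)
        c(s:(s + 5L), s + 10L)))
    }
    hit <- which(stats::runif(n) < config$substitutionRate)
    hit <- setdiff(hit, protected)
    for (i in hit) res[i] <- sample(setdiff(SUBST_POOL, res[i]), 1L)
  }

  # designed type call: majority rule over the canonical (non-terminal)
  # units, mirroring the classifier
  canonTypes <- unitTypes[-config$nRepeats]
  tab <- sort(table(canonTypes), decreasing = TRUE)
  designedType <- if (tab[1L] / length(canonTypes) > 0.5)
    names(tab)[1L] else "mixed"

  keep <- c(1L, n)
  completeness <- "full"
  if (config$fragmentMode %in% c("n_only", "internal")) {
    keep[2L] <- starts[config$nRepeats] + 4L  # cut inside the last hexamer
    completeness <- "n_complete"
  }
  if (config$fragmentMode %in% c("c_only", "internal")) {
    keep[1L] <- config$spLen + 11L  # drop Met, signal and the Tyr-Trp dyad
    completeness <- if (config$fragmentMode == "internal") "internal"
                    else "c_complete"
  }
  residues <- paste(res[keep[1L]:keep[2L]], collapse = "")

  truth <- list(
    cleavageAfter = config$spLen,
    ywPositionMature = 7L,
    cysPositionMature = cysPos,
    ntermLen = config$ntermLen,
    units = data.frame(index = seq_len(config$nRepeats),
                       start = starts, end = ends,
                       status = status, x4 = x4, type = unitTypes),
    stType = designedType,
    completeness = completeness,
    fragmentMode = config$fragmentMode,
    config = config
  )
  list(id = id, residues = residues,
       description = paste0("synthetic ST seed=", config$seed,
                            " type=", designedType,
                            " mode=", config$fragmentMode),
       truth = truth)
}

#' Generate a non-ST decoy sequence
#'
#' Decoys emulate the repeat grammars of the cell-wall protein classes used
#' as negative controls: proline-rich proteins (PRP: PPxx(K/T), PPYV, PPV,
#' P(V/I)YK, PEPK, ... motifs), hydroxyproline-rich glycoproteins (HRGP:
#' Ser-Hyp4 pentapeptides, Hyp written P), glycine-rich proteins (GRP:
#' (Gly-X)n, Gly fraction >= 0.4), arabinogalactan proteins (AGP: Ala-Pro /
#' Ser-Pro / Thr-Pro glycomodules), or a residue-preserving shuffle of a
#' generated ST precursor. All decoys are guaranteed (by grammar for the
#' motif kinds, by rejection-resampling for the shuffle) to carry no
#' (D/E)FEPRP-X4-Y signature.
#'
#' @param kind "prp", "hrgp", "grp", "agp" or "shuffled_st".
#' @param seed RNG seed.
#' @param targetLength approximate sequence length.
#' @return list with \code{id}, \code{residues}, \code{description}.
#' @export
generateDecoy <- function(kind = c("prp", "hrgp", "grp", "agp",
                                   "shuffled_st"),
                          seed = 1L, targetLength = 150L) {
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  res <- switch(kind,
    prp = {
      motifs <- c("PPVYK", "PPHEK", "PPVTK", "PPEYT", "PPYV", "PPV",
                  "PVYK", "PIYK", "PEPK", "PKPE", "PVPPK", "PEPPK",
                  "KKPVPP", "PPTPRPS")
      out <- character(0)
      while (sum(nchar(out)) < targetLength)
        out <- c(out, sample(motifs, 1L))
      paste(out, collapse = "")
    },
    hrgp = {
      blocks <- replicate(ceiling(targetLength / 6L),
        paste0("SPPPP", sample(c("K", "Y", "V", "T", "H"), 1L)))
      paste(blocks, collapse = "")
    },
    grp = {
      x <- sample(c("G", "A", "S", "E", "R", "Q", "H", "Y"),
                  ceiling(targetLength / 2L), replace = TRUE)
      paste(paste0("G", x), collapse = "")
    },
    agp = {
      paste(sample(c("AP", "SP", "TP"), ceiling(targetLength / 2L),
                   replace = TRUE), collapse = "")
    },
    shuffled_st = {
      src <- generateST(stConfig(seed = seed))$residues
      ch <- .chars(src)
      s <- paste(sample(ch), collapse = "")
      while (isSTProtein(s)) s <- paste(sample(ch), collapse = "")
      s
    })
  if (isSTProtein(res))
    stop("internal error: decoy carries the ST signature")  # unreachable
  list(id = paste0("Dec", toupper(substr(kind, 1L, 1L)), seed),
       residues = res,
       description = paste("synthetic decoy", kind, "seed", seed))
}

# 3-letter species code for index i: Aaa, Baa, ... Zaa, Aba, ...
.speciesCode <- function(i) {
  i <- i - 1L
  paste0(LETTERS[i %% 26L + 1L],
         letters[(i %/% 26L) %% 26L + 1L],
         letters[(i %/% 676L) %% 26L + 1L])
}

#' Generate a multi-species synthetic ST family
#'
#' Each clade template defines a base precursor; species are assigned to
#' clades round-robin and each member is derived from its clade base with
#' small within-clade substitution noise (anchor, signal and N-terminal
#' feature positions protected). Between-clade divergence comes from the
#' independent template draws.
#'
#' @param nSpecies number of species (>= number of templates).
#' @param seqsPerSpecies sequences per species.
#' @param cladeTemplates list of [stConfig()] objects (>= 2), or a
#'   character vector of types from which default configs are built.
#' @param seed RNG seed.
#' @param withinNoise within-clade substitution rate.
#' @return list with \code{seqs} (named character vector, description
#'   attribute records clade and species) and \code{truth} (data.frame:
#'   id, species, clade, stType).
#' @export
generateFamily <- function(nSpecies, seqsPerSpecies = 1L,
                           cladeTemplates = c("I", "IIa"),
                           seed = 1L, withinNoise = 0) {
  if (is.character(cladeTemplates))
    cladeTemplates <- lapply(seq_along(cladeTemplates), function(i)
      stConfig(seed = i, stType = cladeTemplates[i]))
  nClades <- length(cladeTemplates)
  stopifnot(nClades >= 2L, nSpecies >= nClades)
  bases <- lapply(seq_len(nClades), function(c) {
    cfg <- cladeTemplates[[c]]
    cfg$seed <- as.integer(seed * 1000L + c)
    generateST(cfg)
  })
  set.seed(as.integer(seed))
  seqs <- character(0)
  desc <- character(0)
  truth <- NULL
  for (i in seq_len(nSpecies)) {
    cl <- (i - 1L) %% nClades + 1L
    base <- bases[[cl]]
    cfg <- cladeTemplates[[cl]]
    protected <- unique(c(
      unlist(lapply(base$truth$units$start, function(s)
        c(s:(s + 5L), s + 10L))),
      1L, cfg$spLen + 1L,                      # Met, mature Arg
      cfg$spLen + 7L, cfg$spLen + 8L,          # Tyr-Trp dyad
      cfg$spLen + base$truth$cysPositionMature # the single Cys
    ))
    for (j in seq_len(seqsPerSpecies)) {
      ch <- .chars(base$residues)
      if (withinNoise > 0) {
        hit <- setdiff(which(stats::runif(length(ch)) < withinNoise),
                       protected)
        for (p in hit) ch[p] <- sample(setdiff(SUBST_POOL, ch[p]), 1L)
      }
      id <- paste0(.speciesCode(i), "ST", j)
      seqs[id] <- paste(ch, collapse = "")
      desc[id] <- paste0("synthetic family clade=", cl,
                         " species=", .speciesCode(i))
      truth <- rbind(truth, data.frame(
        id = id, species = .speciesCode(i), clade = cl,
        stType = base$truth$stType))
    }
  }
  attr(seqs, "description") <- desc
  list(seqs = seqs, truth = truth)
}

#' Synthetic stand-in for the curated 136-sequence family set
#'
#' Builds a fully synthetic dataset whose designed summary statistics match
#' the published characterization of the curated family: 136 sequences of
#' which 72 are full-length, 38 N-terminally complete, 7 C-terminally
#' complete and 19 internal fragments; full-length precursor lengths
#' spanning 103 to 493 aa with size classes near 36% under 150 aa, 41% in
#' 150-250 and 23% over 250; repeat counts from 2 to 17; type fractions
#' near 21% type I and 55% type IIa (plus IIb, III and mixed-pattern
#' sequences). This is a generated stand-in for validating the annotation
#' rules, not the curated sequences themselves.
#'
#' @param seed RNG seed.
#' @return list with \code{seqs} (named character vector) and \code{truth}
#'   (data.frame: id, stType, completeness, lengthFull, nRepeats).
#' @export
generateCuratedSet <- function(seed = 1L) {
  seed <- as.integer(seed)
  nTot <- 136L
  types <- c(rep("I", 29L), rep("IIa", 75L), rep("IIb", 3L),
             rep("III", 18L), rep("mixed", 11L))
  modes <- c(rep("full", 72L), rep("n_only", 38L), rep("c_only", 7L),
             rep("internal", 19L))
  set.seed(seed)
  types <- sample(types)
  modes <- sample(modes)

  # repeat-count classes for the 72 full-length sequences: 26 short
  # (103-149 aa), 30 medium (150-250) and 16 long (251-493); two type-IIa
  # full sequences are pinned to the documented extremes (103 and 493 aa).
  sizeClass <- sample(c(rep("short", 26L), rep("medium", 30L),
                        rep("long", 16L)))
  pins <- which(modes == "full" & types == "IIa")[1:2]

  seqs <- character(0)
  desc <- character(0)
  truth <- NULL
  fullSeen <- 0L
  for (i in seq_len(nTot)) {
    mode <- modes[i]
    type <- types[i]
    if (mode == "full") {
      fullSeen <- fullSeen + 1L
      cls <- sizeClass[fullSeen]
    } else {
      cls <- sample(c("short", "medium", "long"), 1L,
                    prob = c(0.2, 0.5, 0.3))
    }
    nR <- switch(cls,
      short = sample(2:3, 1L),
      medium = sample(4:8, 1L),
      long = sample(9:17, 1L))
    if (type == "mixed") {           # needs an even canonical unit count
      nR <- max(5L, nR + (nR %% 2L == 0L))
      cls <- if (nR <= 3L) "short" else if (nR <= 8L) "medium" else "long"
    }
    rl <- sample(c(22:27), 1L, prob = c(0.05, 0.05, 0.1, 0.45, 0.3, 0.05))
    sp <- sample(19:28, 1L, prob = c(2, 2, 12, 55, 16, 4, 3, 3, 2, 1))
    # N-terminal length from the class length window, respecting the
    # family extremes (103 and 493 aa) and the 14-80 generator bounds
    win <- switch(cls, short = c(103L, 149L), medium = c(150L, 250L),
                  long = c(251L, 493L))
    body <- sp + (nR - 1L) * rl + 13L
    lo <- max(14L, win[1L] - body, 103L - body)
    hi <- max(lo, min(80L, win[2L] - body, 493L - body))
    nterm <- if (lo >= hi) lo else sample(lo:hi, 1L)
    unitTypes <- NULL
    if (type == "mixed") {
      unitTypes <- c(rep(c("IIa", "III"), (nR - 1L) %/% 2L), "IIa")
    }
    if (i == pins[1L]) {                           # 103-aa extreme
      sp <- 22L; nterm <- 43L; nR <- 2L; rl <- 25L; unitTypes <- NULL
    }
    if (i == pins[2L]) {                           # 493-aa extreme
      sp <- 22L; nterm <- 58L; nR <- 17L; rl <- 25L; unitTypes <- NULL
    }
    cfg <- stConfig(seed = seed * 1000L + i, spLen = sp, ntermLen = nterm,
                    nRepeats = nR, repeatLen = rl,
                    stType = if (type == "mixed") "mixed" else type,
                    fragmentMode = mode, unitTypes = unitTypes)
    id <- paste0(.speciesCode(i), "ST", if (type == "I") 1L else 2L)
    rec <- generateST(cfg, id = id)
    seqs[id] <- rec$residues
    desc[id] <- paste("synthetic curated stand-in", type, mode)
    truth <- rbind(truth, data.frame(
      id = id, stType = rec$truth$stType,
      completeness = rec$truth$completeness,
      lengthFull = if (mode == "full") nchar(rec$residues) else NA_integer_,
      nRepeats = nR))
  }
  attr(seqs, "description") <- desc
  list(seqs = seqs, truth = truth)
}
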
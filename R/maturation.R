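# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

.kd <- function(ch) {
  v <- KD_SCALE[ch]
  v[is.na(v)] <- 0   # X and unknowns are neutral
  unname(v)
}

#' Predict the signal-peptide cleavage site
#'
#' ST precursors carry a 19-28 aa signal peptide and their mature protein
#' starts with Arg in nearly all sequences. The heuristic examines candidate
#' cleavage points 19-28: the first candidate whose following residue is Arg
#' and whose hydrophobic-core window (positions 6 to candidate-4) has mean
#' Kyte-Doolittle hydropathy above \code{kdThreshold} is chosen with high
#' confidence. With no Arg-anchored candidate, the candidate with the
#' highest core hydropathy is used and flagged low-confidence; when even
#' that core is not hydrophobic (mean <= \code{kdThreshold}), no signal
#' peptide is called and a warning is issued. An externally determined
#' cleavage site (e.g. from SignalP) can be supplied and is used verbatim.
#'
#' @param residues precursor protein sequence (>= 40 residues).
#' @param suppliedCleavage optional integer: cleave after this position.
#' @param kdThreshold mean hydropathy required of the core window.
#' @return list with \code{cleavageAfter} (integer or NA),
#'   \code{matureStartResidue}, \code{confidence} ("high", "low",
#'   "supplied" or "none").
#' @export
predictMatureStart <- function(residues, suppliedCleavage = NULL,
                               kdThreshold = 1.0) {
  s <- toupper(as.character(residues))
  n <- nchar(s)
  if (!is.null(suppliedCleavage)) {
    cl <- as.integer(suppliedCleavage)
    stopifnot(cl >= 1L, cl < n)
    return(list(cleavageAfter = cl,
                matureStartResidue = substr(s, cl + 1L, cl + 1L),
                confidence = "supplied"))
  }
  if (n < 40L) stop("sequence too short (< 40 aa) for cleavage prediction")
  ch <- .chars(s)
  cand <- 19:28
  cand <- cand[cand + 1L <= n]
  coreMean <- vapply(cand, function(cl)
    mean(.kd(ch[6:(cl - 4L)])), numeric(1))
  argAnch <- which(ch[cand + 1L] == "R" & coreMean > kdThreshold)
  if (length(argAnch)) {
    cl <- cand[argAnch[1L]]
    return(list(cleavageAfter = cl,
                matureStartResidue = ch[cl + 1L],
                confidence = "high"))
  }
  if (max(coreMean) > kdThreshold) {
    cl <- cand[which.max(coreMean)]
    return(list(cleavageAfter = cl,
                matureStartResidue = ch[cl + 1L],
                confidence = "low"))
  }
  warning("no hydrophobic signal-peptide core found; no cleavage called")
  list(cleavageAfter = NA_integer_, matureStartResidue = NA_character_,
       confidence = "none")
}

#' Conserved features of the mature N-terminal region
#'
#' The mature N-terminal region of ST proteins (mature start to the first
#' repeat) starts with Arg, carries a Tyr-Trp dyad at mature positions 7-8
#' (7-9 scanned, to admit the one-residue offset seen in a few sequences)
#' and the single Cys of the mature protein. Absent features yield NA
#' fields; about 16% of ST sequences lack the Cys.
#'
#' @param matureResidues the mature protein sequence (signal removed).
#' @param firstAnchor 1-based position of the first repeat anchor in
#'   mature coordinates (> 1).
#' @return list: \code{ntermLen}, \code{ywPosition}, \code{ywOffsetFlag},
#'   \code{cysPosition}, \code{distYwToCys}, \code{distCysToRepeat1}.
#' @export
ntermFeatures <- function(matureResidues, firstAnchor) {
  s <- toupper(as.character(matureResidues))
  firstAnchor <- as.integer(firstAnchor)
  if (firstAnchor <= 1L) stop("first repeat anchor must be > 1")
  ch <- .chars(s)
  yw <- NA_integer_
  for (p in 7:9) {
    if (p + 1L <= nchar(s) && ch[p] == "Y" && ch[p + 1L] == "W") {
      yw <- p
      break
    }
  }
  pre <- ch[seq_len(min(firstAnchor - 1L, length(ch)))]
  cys <- which(pre == "C")
  cys <- if (length(cys)) cys[1L] else NA_integer_
  list(
    ntermLen = firstAnchor - 1L,
    ywPosition = yw,
    ywOffsetFlag = !is.na(yw) && yw > 7L,
    cysPosition = cys,
    distYwToCys = if (!is.na(yw) && !is.na(cys)) cys - yw else NA_integer_,
    distCysToRepeat1 = if (!is.na(cys)) firstAnchor - cys else NA_integer_
  )
}

#' Classify sequence completeness
#'
#' A deduced protein is N-complete when (in nucleotide mode) an in-frame
#' stop precedes the first Met, or when a signal peptide and the mature
#' Tyr-Trp dyad were both found. It is C-complete when a terminal stop
#' codon was seen without a detected frameshift, or when the sequence ends
#' with Tyr followed by two or three residues (Tyr at position -3 or -4).
#' Full-length means both; internal means neither.
#'
#' @param residues the analysed protein sequence.
#' @param matureModel result of [predictMatureStart()] (or NULL).
#' @param ntermModel result of [ntermFeatures()] (or NULL).
#' @param nucleotideContext optional list with logicals
#'   \code{stopBeforeMet}, \code{terminalStop}, \code{frameshift}.
#' @return list with \code{value} ("full", "n_complete", "c_complete",
#'   "internal") and \code{evidence} (character vector of satisfied rules).
#' @export
classifyCompleteness <- function(residues, matureModel = NULL,
                                 ntermModel = NULL,
                                 nucleotideContext = NULL) {
  s <- toupper(as.character(residues))
  n <- nchar(s)
  evidence <- character(0)

  signalFound <- !is.null(matureModel) &&
    !is.na(matureModel$cleavageAfter) &&
    matureModel$confidence %in% c("high", "low", "supplied")
  ywFound <- !is.null(ntermModel) && !is.na(ntermModel$ywPosition)
  stopBeforeMet <- isTRUE(nucleotideContext$stopBeforeMet)

  nComplete <- stopBeforeMet || (signalFound && ywFound)
  if (stopBeforeMet) evidence <- c(evidence, "stop_before_met")
  if (signalFound) evidence <- c(evidence, "signal_peptide")
  if (ywFound) evidence <- c(evidence, "yw_dyad")

  terminalStop <- isTRUE(nucleotideContext$terminalStop) &&
    !isTRUE(nucleotideContext$frameshift)
  ch <- .chars(s)
  tyrTail <- n >= 4L && (ch[n - 2L] == "Y" || ch[n - 3L] == "Y")
  cComplete <- terminalStop || tyrTail
  if (terminalStop) evidence <- c(evidence, "terminal_stop")
  if (tyrTail) evidence <- c(evidence, "terminal_tyr_pattern")

  value <- if (nComplete && cComplete) "full"
           else if (nComplete) "n_complete"
           else if (cComplete) "c_complete"
           else "internal"
  list(value = value, evidence = evidence)
}
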
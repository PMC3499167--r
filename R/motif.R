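#' Scan a protein for the ST repeat signature (D/E)FEPRP-X4-Y
#'
#' Reports every position at which a repeat anchor starts: the hexapeptide
#' \code{[DE]FEPRP} (within \code{maxHexamerMismatch} mismatches; the first
#' position counts as matching for either D or E) followed by four arbitrary
#' residues and a tyrosine at offset 11. The tyrosine requirement is never
#' relaxed. Overlapping candidates (closer than the 11-residue signature)
#' are resolved leftmost-first.
#'
#' @param residues a single protein sequence (character or AAString).
#' @param maxHexamerMismatch allowed mismatches in the hexapeptide
#'   (default 0 = exact).
#' @return integer vector of 1-based anchor positions (empty when none).
#' @examples
#' scanMotif("RKDFEPRPNVSAY")  # 3
#' scanMotif("EFEPRPKVTAYQQ")  # 1, the E-variant
#' scanMotif("DFEPRPNVSA")     # no conserved Tyr -> empty
#' @export
scanMotif <- function(residues, maxHexamerMismatch = 0L) {
  s <- toupper(as.character(residues))
  n <- nchar(s)
  if (n < 11L) return(integer(0))
  ch <- .chars(s)
  idx <- seq_len(n - 10L)
  mm <- (!(ch[idx] %in% c("D", "E"))) +
    (ch[idx + 1L] != "F") + (ch[idx + 2L] != "E") +
    (ch[idx + 3L] != "P") + (ch[idx + 4L] != "R") +
    (ch[idx + 5L] != "P")
  cand <- idx[mm <= maxHexamerMismatch & ch[idx + 10L] == "Y"]
  if (length(cand) < 2L) return(cand)
  anchors <- cand[1L]
  last <- cand[1L]
  for (p in cand[-1L]) {
    if (p >= last + 11L) {
      anchors <- c(anchors, p)
      last <- p
    }
  }
  anchors
}

#' Is a sequence an ST protein?
#'
#' A sequence is considered ST when it carries at least one occurrence of
#' the repeat signature (D/E)FEPRP-X4-Y.
#'
#' @inheritParams scanMotif
#' @return logical.
#' @export
isSTProtein <- function(residues, maxHexamerMismatch = 0L) {
  length(scanMotif(residues, maxHexamerMismatch)) > 0L
}

# modal length with ties resolved to the smaller value
.modalLength <- function(lens) {
  if (!length(lens)) return(NA_integer_)
  tab <- table(lens)
  as.integer(min(as.integer(names(tab)[tab == max(tab)])))
}

# uniform / alternating / heterogeneous over the regular unit lengths
.lengthPattern <- function(lens) {
  if (length(lens) <= 1L || length(unique(lens)) == 1L) return("uniform")
  if (length(unique(lens)) == 2L && length(lens) >= 2L) {
    alt <- all(lens[-1L] != lens[-length(lens)])
    if (alt) return("alternating")
  }
  "heterogeneous"
}

#' Segment the tandem-repeat region of an ST protein
#'
#' Each anchor starts a new repeat unit: unit k spans anchor k to
#' anchor k+1 minus 1, and the last unit runs from the last anchor to the
#' C-terminus. The last unit is flagged \code{truncated_terminal} when
#' shorter than the modal canonical length (or, when there is a single
#' unit with no full unit to define a mode, shorter than 22 aa, the lower
#' bound of regular ST repeat lengths). A fuzzy pre-scan (1 hexapeptide
#' mismatch, tyrosine still required) over at most two modal lengths
#' upstream of the first anchor can add \code{imperfect_leading} units.
#'
#' The returned [RepeatRegion-class] carries the Psim score (when >= 2
#' units) and the majority consensus of the modal-length units (when >= 2).
#'
#' @param residues the protein sequence.
#' @param anchors anchor positions from [scanMotif()]; computed when NULL.
#' @param fuzzyLeading logical, run the imperfect-leading pre-scan.
#' @return a [RepeatRegion-class] object.
#' @examples
#' s <- paste0(strrep("DFEPRPNVSAYDNDADKSKAKKDFK", 2),
#'             "DFEPRPNVSAYDN")
#' segmentRepeats(s)
#' @export
segmentRepeats <- function(residues, anchors = NULL, fuzzyLeading = TRUE) {
  s <- toupper(as.character(residues))
  n <- nchar(s)
  if (is.null(anchors)) anchors <- scanMotif(s)
  if (length(anchors) == 0L)
    stop("not an ST signature: no (D/E)FEPRP-X4-Y anchor found")
  anchors <- sort(unique(as.integer(anchors)))
  starts <- anchors
  ends <- c(anchors[-1L] - 1L, n)
  lens <- ends - starts + 1L
  status <- rep("canonical", length(starts))

  nReg <- length(starts) - 1L          # units with both boundaries anchored
  modal <- if (nReg >= 1L) .modalLength(lens[seq_len(nReg)]) else NA_integer_
  lastLen <- lens[length(lens)]
  truncatedRef <- if (!is.na(modal)) modal else 22L
  if (lastLen < truncatedRef)
    status[length(status)] <- "truncated_terminal"
  if (is.na(modal) && status[length(status)] != "truncated_terminal")
    modal <- lastLen

  # fuzzy pre-scan for imperfect leading repeats
  if (fuzzyLeading && !is.na(modal)) {
    lo <- max(1L, starts[1L] - 2L * modal)
    if (starts[1L] - lo >= 11L) {
      pre <- substr(s, lo, starts[1L] - 1L)
      preAnch <- scanMotif(pre, maxHexamerMismatch = 1L) + lo - 1L
      preAnch <- preAnch[preAnch + 10L < starts[1L]]
      if (length(preAnch)) {
        pStarts <- preAnch
        pEnds <- c(preAnch[-1L] - 1L, starts[1L] - 1L)
        starts <- c(pStarts, starts)
        ends <- c(pEnds, ends)
        lens <- ends - starts + 1L
        status <- c(rep("imperfect_leading", length(pStarts)), status)
      }
    }
  }

  seqs <- substring(s, starts, ends)
  units <- data.frame(
    index = seq_along(starts),
    start = starts, end = ends, length = lens, seq = seqs,
    hexamerFirst = substring(seqs, 1L, 1L),
    x4 = ifelse(lens >= 10L, substring(seqs, 7L, 10L), NA_character_),
    anchorTyrOffset = ifelse(lens >= 11L &
                               substring(seqs, 11L, 11L) == "Y",
                             11L, NA_integer_),
    status = status,
    stringsAsFactors = FALSE
  )

  regular <- units$length[units$status == "canonical"]
  pattern <- .lengthPattern(regular)

  region <- new("RepeatRegion",
    units = units,
    modalLength = as.integer(modal),
    lengthPattern = pattern,
    psim = NA_real_,
    consensus = NA_character_
  )
  if (nrow(units) >= 2L) region@psim <- psimScore(region)
  if (!is.na(modal)) {
    eligible <- units$status == "canonical" & units$length >= modal
    if (sum(eligible) >= 2L)
      region@consensus <- deriveConsensus(region)
  }
  region
}

# column-majority consensus with first-unit tie-break; used by both
# deriveConsensus (threshold > 0) and psimScore (threshold 0)
.columnConsensus <- function(seqs, L, threshold) {
  vapply(seq_len(L), function(j) {
    resj <- substring(seqs, j, j)
    resj <- resj[nchar(seqs) >= j]
    # table over levels in first-occurrence order: which.max breaks ties
    # in favour of the residue seen first (unit order)
    tab <- table(factor(resj, levels = unique(resj)))
    top <- names(tab)[which.max(tab)]
    if (max(tab) / length(resj) >= threshold) top else "X"
  }, character(1))
}

#' Majority consensus of the modal-length repeat units
#'
#' Units are anchored at position 1 and trimmed to the modal length; per
#' column, the most frequent residue is emitted when its frequency reaches
#' \code{threshold} (default 0.5), otherwise \code{X}. Frequency ties are
#' broken by the residue occurring first in unit order.
#'
#' @param region a [RepeatRegion-class].
#' @param threshold minimum majority frequency for a consensus residue.
#' @return consensus string of modal length.
#' @export
deriveConsensus <- function(region, threshold = 0.5) {
  stopifnot(is(region, "RepeatRegion"))
  u <- region@units
  modal <- region@modalLength
  if (is.na(modal)) stop("modal length undefined")
  el <- u$status == "canonical" & u$length >= modal
  if (sum(el) < 2L)
    stop("need >= 2 canonical units of modal length for a consensus")
  seqs <- substring(u$seq[el], 1L, modal)
  paste(.columnConsensus(seqs, modal, threshold), collapse = "")
}

#' Repeat-perfection score (Psim)
#'
#' The fraction of repeat-unit positions that equal the column-wise
#' majority consensus of the anchored repeat alignment. All units are
#' compared, the truncated terminal unit over its own length only. The
#' column consensus uses plain majority (threshold 0) with frequency ties
#' broken in favour of the first unit. The score is 1 exactly when all
#' units are identical over their compared spans; values of 0.7 and above
#' indicate perfect or nearly perfect tandem repeats.
#'
#' @param region a [RepeatRegion-class] with >= 2 units.
#' @return numeric in [0, 1].
#' @export
psimScore <- function(region) {
  stopifnot(is(region, "RepeatRegion"))
  seqs <- region@units$seq
  if (length(seqs) < 2L) stop("Psim requires >= 2 repeat units")
  L <- max(nchar(seqs))
  cons <- .columnConsensus(seqs, L, threshold = 0)
  total <- 0L
  matches <- 0L
  for (j in seq_len(L)) {
    resj <- substring(seqs, j, j)
    resj <- resj[nchar(seqs) >= j]
    total <- total + length(resj)
    matches <- matches + sum(resj == cons[j])
  }
  matches / total
}

#' Count DUF2775-like domain windows (proxy)
#'
#' The DUF2775 domain spans roughly 20 residues of the non-repeat region
#' plus two tandem repeats and one truncated repeat (~135 aa). As a proxy
#' (not a CDD reproduction), complete domains are counted as non-overlapping
#' windows of 3 consecutive repeat units containing at least 2 canonical
#' units, scanned from the N-terminus; 1-2 trailing units count as one
#' truncated domain.
#'
#' @param region a [RepeatRegion-class].
#' @param ntermLen length of the mature N-terminal region (recorded for
#'   provenance; the proxy count depends only on the units).
#' @return named integer vector \code{c(complete=, truncated=)}.
#' @examples
#' # 7 units -> 2 complete windows + 1 trailing unit
#' @export
countDufLikeDomains <- function(region, ntermLen = NA_integer_) {
  stopifnot(is(region, "RepeatRegion"))
  st <- region@units$status
  nU <- length(st)
  complete <- 0L
  leftover <- 0L
  i <- 1L
  while (i <= nU) {
    if (i + 2L <= nU && sum(st[i:(i + 2L)] == "canonical") >= 2L) {
      complete <- complete + 1L
      i <- i + 3L
    } else {
      leftover <- leftover + 1L
      i <- i + 1L
    }
  }
  c(complete = complete, truncated = as.integer(leftover > 0L))
}
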
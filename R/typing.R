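#' N-glycosylation sequons (PROSITE PS00001)
#'
#' Reports all matches of the N-glycosylation acceptor pattern
#' N-{P}-[ST]-{P}: Asn, any residue but Pro, Ser or Thr, and (when a
#' following residue exists) anything but Pro. Overlapping matches are all
#' reported.
#'
#' @param residues protein sequence.
#' @param region optional [RepeatRegion-class]; when given, each site is
#'   assigned the index of the repeat unit containing its Asn.
#' @return data.frame with \code{position} (of the Asn), \code{sequon}
#'   (the 3-residue core) and \code{withinRepeat} (unit index or NA).
#' @examples
#' nglycSites("ANVSA")  # one site, sequon NVS
#' nglycSites("ANPSA")  # none: Pro at the middle position
#' nglycSites("ANVSP")  # none: Pro after the sequon
#' @export
nglycSites <- function(residues, region = NULL) {
  s <- toupper(as.character(residues))
  n <- nchar(s)
  out <- data.frame(position = integer(0), sequon = character(0),
                    withinRepeat = integer(0))
  if (n < 3L) return(out)
  ch <- .chars(s)
  idx <- seq_len(n - 2L)
  ok <- ch[idx] == "N" & ch[idx + 1L] != "P" &
    ch[idx + 2L] %in% c("S", "T") &
    (idx + 3L > n | c(ch[-seq_len(3L)], "")[idx] != "P")
  pos <- idx[ok]
  if (!length(pos)) return(out)
  within <- rep(NA_integer_, length(pos))
  if (!is.null(region)) {
    u <- region@units
    for (i in seq_along(pos)) {
      hit <- which(u$start <= pos[i] & u$end >= pos[i])
      if (length(hit)) within[i] <- u$index[hit[1L]]
    }
  }
  data.frame(position = pos,
             sequon = substring(s, pos, pos + 2L),
             withinRepeat = within)
}

#' X4 category of one repeat unit
#'
#' The four residues between the hexapeptide and the conserved Tyr (unit
#' positions 7-10) define the ST types: Ser at position 7 is type I (SxTx,
#' no sequon); Asn at 7 with Ser/Thr at 9 is type IIa (NxSx, carrying an
#' N-glycosylation sequon); Asn at 7 with Phe/Leu at 9 is type IIb
#' (Nx(F/L)x, no sequon); Asp or Thr at 7 is type III (DxT/Sx).
#'
#' @param unitSeq the repeat-unit sequence (>= 11 residues).
#' @return one of "I", "IIa", "IIb", "III", "other".
#' @examples
#' x4Category("DFEPRPSKTVY")  # "I"
#' x4Category("DFEPRPNVSAY")  # "IIa"
#' x4Category("DFEPRPNFLSY")  # "IIb"
#' @export
x4Category <- function(unitSeq) {
  s <- toupper(as.character(unitSeq))
  if (nchar(s) < 11L) stop("repeat unit shorter than 11 residues")
  p7 <- substr(s, 7L, 7L)
  p9 <- substr(s, 9L, 9L)
  if (p7 == "S") return("I")
  if (p7 == "N" && p9 %in% c("S", "T")) return("IIa")
  if (p7 == "N" && p9 %in% c("F", "L")) return("IIb")
  if (p7 %in% c("D", "T")) return("III")
  "other"
}

#' Classify a protein into an ST type
#'
#' Majority vote of the X4 categories over the canonical repeat units
#' (imperfect leading and truncated terminal units are excluded). A strict
#' majority (> 0.5) assigns the type; otherwise the call is "mixed" and the
#' component categories are listed by decreasing share.
#'
#' @param region a [RepeatRegion-class] with >= 1 canonical unit.
#' @return list: \code{stType}, \code{majorityFraction},
#'   \code{perRepeatPatterns} (data.frame index/x4/category over canonical
#'   units), \code{mixture} (NULL unless mixed).
#' @export
classifyProtein <- function(region) {
  stopifnot(is(region, "RepeatRegion"))
  u <- region@units[region@units$status == "canonical", , drop = FALSE]
  u <- u[nchar(u$seq) >= 11L, , drop = FALSE]
  if (nrow(u) == 0L) stop("no canonical repeat units to classify")
  cats <- vapply(u$seq, x4Category, character(1), USE.NAMES = FALSE)
  tab <- sort(table(cats), decreasing = TRUE)
  shares <- as.numeric(tab) / nrow(u)
  top <- shares[1L]
  if (top > 0.5) {
    stType <- names(tab)[1L]
    mixture <- NULL
  } else {
    stType <- "mixed"
    mixture <- names(tab)
  }
  list(
    stType = stType,
    majorityFraction = top,
    perRepeatPatterns = data.frame(index = u$index, x4 = u$x4,
                                   category = cats),
    mixture = mixture
  )
}

#' Assign ST family names within one species
#'
#' The unique type-I sequence of a species is designated ST1; all other
#' sequences are numbered ST2 and following in input order. Two type-I
#' sequences in the same species raise a warning; the first keeps the ST1
#' name.
#'
#' @param stTypes character vector of type calls, in input order.
#' @param speciesCode 3-letter species code (e.g. "Car").
#' @param ids optional names for the result (defaults to input order).
#' @return named character vector of assigned ids.
#' @examples
#' assignFamilyNames(c("IIa", "I"), "Psa")  # PsaST2, PsaST1
#' @export
assignFamilyNames <- function(stTypes, speciesCode, ids = NULL) {
  stopifnot(grepl("^[A-Za-z]{3}$", speciesCode))
  typeI <- which(stTypes == "I")
  if (length(typeI) > 1L) {
    warning("multiple type-I sequences in species ", speciesCode,
            "; first kept as ST1")
    typeI <- typeI[1L]
  }
  out <- character(length(stTypes))
  counter <- 2L
  for (i in seq_along(stTypes)) {
    if (length(typeI) && i == typeI) {
      out[i] <- paste0(speciesCode, "ST1")
    } else {
      out[i] <- paste0(speciesCode, "ST", counter)
      counter <- counter + 1L
    }
  }
  names(out) <- if (is.null(ids)) seq_along(stTypes) else ids
  out
}
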
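#' RepeatRegion: the segmented tandem-repeat region of one protein
#'
#' Holds the ordered repeat units detected in a protein, the modal canonical
#' unit length, the length pattern of the regular units, the repeat-perfection
#' score (Psim) and the majority consensus of the modal-length units.
#'
#' The \code{units} slot is a data.frame with one row per repeat unit and
#' columns \code{index}, \code{start}, \code{end} (1-based inclusive residue
#' coordinates on the input sequence), \code{length}, \code{seq},
#' \code{hexamerFirst} (the D/E at unit position 1), \code{x4} (unit
#' positions 7-10), \code{anchorTyrOffset} (always 11 for canonical units)
#' and \code{status} (one of \code{canonical}, \code{imperfect_leading},
#' \code{truncated_terminal}).
#'
#' @slot units data.frame of repeat units (see Details).
#' @slot modalLength integer, most frequent canonical unit length
#'   (ties resolved to the smaller length); NA when no full unit exists.
#' @slot lengthPattern character, one of \code{uniform},
#'   \code{alternating}, \code{heterogeneous}.
#' @slot psim numeric in [0,1]; NA when fewer than 2 units.
#' @slot consensus character; majority consensus over modal-length canonical
#'   units, NA when fewer than 2 such units.
#'
#' @seealso [segmentRepeats()], [psimScore()], [deriveConsensus()]
#' @exportClass RepeatRegion
setClass("RepeatRegion",
  representation(
    units = "data.frame",
    modalLength = "integer",
    lengthPattern = "character",
    psim = "numeric",
    consensus = "character"
  )
)

setValidity("RepeatRegion", function(object) {
  u <- object@units
  need <- c("index", "start", "end", "length", "seq", "hexamerFirst",
            "x4", "anchorTyrOffset", "status")
  if (!all(need %in% names(u)))
    return(paste("units must have columns:", paste(need, collapse = ", ")))
  if (nrow(u) == 0L) return("units must contain at least one repeat")
  if (is.unsorted(u$start, strictly = TRUE))
    return("units must be ordered by start")
  if (any(u$end < u$start)) return("unit end before start")
  if (nrow(u) > 1L) {
    gaps <- u$start[-1L] - u$end[-nrow(u)]
    if (any(gaps != 1L))
      return("units must be contiguous and non-overlapping")
  }
  if (!is.na(object@psim) && (object@psim < 0 || object@psim > 1))
    return("psim must lie in [0, 1]")
  if (!object@lengthPattern %in% c("uniform", "alternating", "heterogeneous"))
    return("unknown lengthPattern")
  bad <- setdiff(u$status,
                 c("canonical", "imperfect_leading", "truncated_terminal"))
  if (length(bad)) return(paste("unknown unit status:", bad[1L]))
  TRUE
})

#' STAnnotation: full per-protein annotation result
#'
#' The result of running the annotation pipeline on one protein sequence:
#' acceptance as an ST protein, signal-peptide cleavage, mature N-terminal
#' features, the segmented repeat region, the X4 type call, N-glycosylation
#' sequons, completeness call and composition statistics.
#'
#' @slot seqId character sequence identifier.
#' @slot residues character, the analysed (precursor) sequence.
#' @slot accepted logical, TRUE when the ST signature was found.
#' @slot reason character, rejection reason when \code{accepted} is FALSE.
#' @slot cleavageAfter integer, signal-peptide length (NA when not found).
#' @slot signalConfidence character: "high", "low", "supplied" or "none".
#' @slot mature list of mature N-terminal features: \code{ntermLen},
#'   \code{ywPosition}, \code{ywOffsetFlag}, \code{cysPosition},
#'   \code{distYwToCys}, \code{distCysToRepeat1} (mature coordinates).
#' @slot region RepeatRegion or NULL.
#' @slot typeCall list: \code{stType}, \code{majorityFraction},
#'   \code{perRepeatPatterns} (data.frame of x4/category), \code{mixture}.
#' @slot glycoSites data.frame: \code{position}, \code{sequon},
#'   \code{withinRepeat}.
#' @slot completeness character: "full", "n_complete", "c_complete",
#'   "internal".
#' @slot evidence character vector of satisfied completeness rules.
#' @slot composition list, see [compositionReport()].
#'
#' @seealso [annotateSequence()], [annotateDataset()]
#' @exportClass STAnnotation
setClass("STAnnotation",
  representation(
    seqId = "character",
    residues = "character",
    accepted = "logical",
    reason = "character",
    cleavageAfter = "integer",
    signalConfidence = "character",
    mature = "list",
    region = "ANY",
    typeCall = "list",
    glycoSites = "data.frame",
    completeness = "character",
    evidence = "character",
    composition = "list"
  )
)

setValidity("STAnnotation", function(object) {
  if (length(object@seqId) != 1L) return("seqId must be length 1")
  if (!is.null(object@region) && !is(object@region, "RepeatRegion"))
    return("region must be a RepeatRegion or NULL")
  if (object@accepted && is.null(object@region))
    return("accepted annotations must carry a RepeatRegion")
  if (length(object@completeness) == 1L &&
      !object@completeness %in%
        c("full", "n_complete", "c_complete", "internal", NA_character_))
    return("unknown completeness value")
  TRUE
})

## ------------------------------------------------------------------------
## Generics and accessors

#' @rdname RepeatRegion-class
#' @param x,object a \code{RepeatRegion} or \code{STAnnotation}
#' @export
setGeneric("repeatUnits", function(x) standardGeneric("repeatUnits"))
#' @rdname RepeatRegion-class
#' @export
setMethod("repeatUnits", "RepeatRegion", function(x) x@units)
#' @rdname RepeatRegion-class
#' @export
setMethod("repeatUnits", "STAnnotation", function(x)
  if (is.null(x@region)) NULL else x@region@units)

#' @rdname RepeatRegion-class
#' @export
setGeneric("modalLength", function(x) standardGeneric("modalLength"))
#' @rdname RepeatRegion-class
#' @export
setMethod("modalLength", "RepeatRegion", function(x) x@modalLength)

#' @rdname RepeatRegion-class
#' @export
setGeneric("psim", function(x) standardGeneric("psim"))
#' @rdname RepeatRegion-class
#' @export
setMethod("psim", "RepeatRegion", function(x) x@psim)
#' @rdname RepeatRegion-class
#' @export
setMethod("psim", "STAnnotation", function(x)
  if (is.null(x@region)) NA_real_ else x@region@psim)

#' @rdname RepeatRegion-class
#' @export
setGeneric("consensusSeq", function(x) standardGeneric("consensusSeq"))
#' @rdname RepeatRegion-class
#' @export
setMethod("consensusSeq", "RepeatRegion", function(x) x@consensus)

#' @rdname STAnnotation-class
#' @export
setGeneric("stType", function(x) standardGeneric("stType"))
#' @rdname STAnnotation-class
#' @export
setMethod("stType", "STAnnotation", function(x) x@typeCall$stType)

#' @rdname STAnnotation-class
#' @export
setGeneric("completeness", function(x) standardGeneric("completeness"))
#' @rdname STAnnotation-class
#' @export
setMethod("completeness", "STAnnotation", function(x) x@completeness)

#' @rdname STAnnotation-class
#' @export
setGeneric("repeatRegion", function(x) standardGeneric("repeatRegion"))
#' @rdname STAnnotation-class
#' @export
setMethod("repeatRegion", "STAnnotation", function(x) x@region)

#' @rdname STAnnotation-class
#' @export
setGeneric("glycoSites", function(x) standardGeneric("glycoSites"))
#' @rdname STAnnotation-class
#' @export
setMethod("glycoSites", "STAnnotation", function(x) x@glycoSites)

setMethod("show", "RepeatRegion", function(object) {
  u <- object@units
  cat("RepeatRegion with", nrow(u), "units (",
      sum(u$status == "canonical"), "canonical )\n")
  cat("  span:", min(u$start), "-", max(u$end),
      " modal length:", object@modalLength,
      " pattern:", object@lengthPattern, "\n")
  cat("  Psim:", if (is.na(object@psim)) "NA" else
    format(object@psim, digits = 4), "\n")
  if (!is.na(object@consensus))
    cat("  consensus:", object@consensus, "\n")
  invisible(NULL)
})

setMethod("show", "STAnnotation", function(object) {
  cat("STAnnotation for", object@seqId,
      "(", nchar(object@residues), "aa )\n")
  if (!object@accepted) {
    cat("  rejected:", object@reason, "\n")
    return(invisible(NULL))
  }
  cat("  signal peptide: cleavage after",
      ifelse(is.na(object@cleavageAfter), "NA", object@cleavageAfter),
      "(", object@signalConfidence, ")\n")
  cat("  repeats:", nrow(object@region@units),
      " type:", object@typeCall$stType,
      " completeness:", object@completeness, "\n")
  cat("  Psim:", format(psim(object), digits = 4),
      " N-glyc sites:", nrow(object@glycoSites), "\n")
  invisible(NULL)
})
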
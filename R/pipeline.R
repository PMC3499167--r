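#' Annotate one protein sequence
#'
#' Runs the full per-sequence analysis: signature scan, repeat segmentation,
#' signal-peptide / mature-feature delineation, completeness call, X4 type
#' classification, N-glycosylation sequons, composition and Psim. Sequences
#' without the (D/E)FEPRP-X4-Y signature are returned as rejected
#' annotations with a reason.
#'
#' @param residues protein sequence.
#' @param id sequence identifier.
#' @param suppliedCleavage optional externally determined cleavage site.
#' @param fuzzyHexamer mismatches allowed in the hexapeptide scan
#'   (0 by default; the conserved Tyr is never relaxed).
#' @param nucleotideContext optional list passed to
#'   [classifyCompleteness()].
#' @return an [STAnnotation-class] object.
#' @export
annotateSequence <- function(residues, id = "seq", suppliedCleavage = NULL,
                             fuzzyHexamer = 0L, nucleotideContext = NULL) {
  s <- toupper(as.character(residues))
  anchors <- scanMotif(s, maxHexamerMismatch = fuzzyHexamer)
  if (!length(anchors)) {
    return(new("STAnnotation",
      seqId = id, residues = s, accepted = FALSE,
      reason = "no ST signature ((D/E)FEPRP-X4-Y not found)",
      cleavageAfter = NA_integer_, signalConfidence = "none",
      mature = list(), region = NULL, typeCall = list(),
      glycoSites = data.frame(), completeness = NA_character_,
      evidence = character(0), composition = list()))
  }
  region <- segmentRepeats(s, anchors)

  mm <- if (!is.null(suppliedCleavage)) {
    predictMatureStart(s, suppliedCleavage = suppliedCleavage)
  } else if (nchar(s) >= 40L) {
    tryCatch(suppressWarnings(predictMatureStart(s)),
             error = function(e) NULL)
  } else NULL
  cl <- if (!is.null(mm)) mm$cleavageAfter else NA_integer_
  conf <- if (!is.null(mm)) mm$confidence else "none"
  # a cleavage at or beyond the first repeat cannot be a signal peptide
  firstAnchor <- min(region@units$start)
  if (!is.na(cl) && cl >= firstAnchor - 1L) {
    cl <- NA_integer_
    conf <- "none"
    mm <- list(cleavageAfter = NA_integer_,
               matureStartResidue = NA_character_, confidence = "none")
  }

  mature <- if (!is.na(cl)) substr(s, cl + 1L, nchar(s)) else s
  anchorMature <- firstAnchor - ifelse(is.na(cl), 0L, cl)
  nf <- if (anchorMature > 1L) {
    ntermFeatures(mature, anchorMature)
  } else list(ntermLen = anchorMature - 1L, ywPosition = NA_integer_,
              ywOffsetFlag = FALSE, cysPosition = NA_integer_,
              distYwToCys = NA_integer_, distCysToRepeat1 = NA_integer_)
  # the dyad is a mature-protein feature; without a signal peptide it
  # cannot support N-completeness
  nfForCall <- nf
  if (is.na(cl)) nfForCall$ywPosition <- NA_integer_

  comp <- classifyCompleteness(s, matureModel = mm, ntermModel = nfForCall,
                               nucleotideContext = nucleotideContext)
  typeCall <- classifyProtein(region)
  glyco <- nglycSites(s, region)

  new("STAnnotation",
    seqId = id, residues = s, accepted = TRUE, reason = NA_character_,
    cleavageAfter = as.integer(cl), signalConfidence = conf,
    mature = nf, region = region, typeCall = typeCall,
    glycoSites = glyco, completeness = comp$value,
    evidence = comp$evidence,
    composition = unclass(compositionReport(mature)))
}

#' Annotate a FASTA dataset and summarize it
#'
#' Applies [annotateSequence()] to every sequence and aggregates the
#' dataset-level statistics reported for the family: completeness counts,
#' full-length size range and size classes, repeat-count range and
#' repeat-length histogram, type fractions, the fractions of full-length
#' sequences with Psim above 0.7 / 0.8 / 0.9, and the charged-fraction
#' range. Every input sequence appears exactly once, as accepted or
#' rejected.
#'
#' @param x FASTA path, AAStringSet, or named character vector.
#' @param cleavageSidecar optional TSV path (or data.frame) with columns
#'   \code{seq_id} and \code{cleavage_after} supplying external cleavage
#'   sites.
#' @param fuzzyHexamer passed to [annotateSequence()].
#' @return list with \code{annotations} (list of [STAnnotation-class]),
#'   \code{rejected} (data.frame id/reason) and \code{summary} (list, see
#'   [writeReport()]).
#' @export
annotateDataset <- function(x, cleavageSidecar = NULL, fuzzyHexamer = 0L) {
  seqs <- if (is.character(x) && length(x) == 1L && file.exists(x)) {
    readFasta(x)
  } else if (is(x, "XStringSet")) {
    setNames(as.character(x), names(x))
  } else x
  if (!length(seqs)) stop("empty input")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")

  sidecar <- NULL
  if (!is.null(cleavageSidecar)) {
    sidecar <- if (is.data.frame(cleavageSidecar)) cleavageSidecar
               else utils::read.delim(cleavageSidecar)
    stopifnot(all(c("seq_id", "cleavage_after") %in% names(sidecar)))
  }

  anns <- vector("list", length(seqs))
  names(anns) <- names(seqs)
  for (id in names(seqs)) {
    supplied <- NULL
    if (!is.null(sidecar) && id %in% sidecar$seq_id)
      supplied <- sidecar$cleavage_after[match(id, sidecar$seq_id)]
    anns[[id]] <- annotateSequence(seqs[[id]], id = id,
                                   suppliedCleavage = supplied,
                                   fuzzyHexamer = fuzzyHexamer)
  }
  acc <- Filter(function(a) a@accepted, anns)
  rej <- Filter(function(a) !a@accepted, anns)
  rejected <- data.frame(
    id = vapply(rej, function(a) a@seqId, character(1)),
    reason = vapply(rej, function(a) a@reason, character(1)),
    row.names = NULL)
  list(annotations = anns, rejected = rejected,
       summary = datasetSummary(acc))
}

#' Dataset-level summary statistics
#'
#' @param annotations list of accepted [STAnnotation-class] objects.
#' @return list of summary statistics (see [annotateDataset()]).
#' @export
datasetSummary <- function(annotations) {
  annotations <- Filter(function(a) a@accepted, annotations)
  n <- length(annotations)
  if (n == 0L) {
    return(list(nSequences = 0L, completeness = NULL, fullLength = NULL,
                lengthClasses = NULL, repeats = NULL, typeFractions = NULL,
                psimFractions = NULL, chargedRange = NULL))
  }
  compl <- vapply(annotations, function(a) a@completeness, character(1))
  complCounts <- vapply(c("full", "n_complete", "c_complete", "internal"),
                        function(v) sum(compl == v), integer(1))
  lens <- vapply(annotations, function(a) nchar(a@residues), integer(1))
  fullLens <- lens[compl == "full"]
  classes <- if (length(fullLens)) c(
    under150 = .roundHalfUp(100 * mean(fullLens < 150)),
    from150to250 = .roundHalfUp(100 * mean(fullLens >= 150 &
                                             fullLens <= 250)),
    over250 = .roundHalfUp(100 * mean(fullLens > 250))) else NULL
  # repeat-count variability is a full-length statistic (fragments
  # understate it); fall back to all accepted sequences when no
  # full-length sequence is present
  repCounts <- vapply(annotations, function(a)
    nrow(a@region@units), integer(1))
  if (any(compl == "full")) repCounts <- repCounts[compl == "full"]
  unitLens <- unlist(lapply(annotations, function(a) {
    u <- a@region@units
    u$length[u$status == "canonical"]
  }))
  types <- vapply(annotations, function(a)
    a@typeCall$stType, character(1))
  typeFractions <- vapply(c("I", "IIa", "IIb", "III", "mixed", "other"),
    function(t) .roundHalfUp(100 * mean(types == t)), numeric(1))
  psims <- vapply(annotations, function(a) psim(a), numeric(1))
  psimFull <- psims[compl == "full" & !is.na(psims)]
  psimFractions <- if (length(psimFull)) c(
    over0.7 = .roundHalfUp(100 * mean(psimFull > 0.7)),
    over0.8 = .roundHalfUp(100 * mean(psimFull > 0.8)),
    over0.9 = .roundHalfUp(100 * mean(psimFull > 0.9))) else NULL
  charged <- vapply(annotations, function(a)
    a@composition$fracCharged, numeric(1))
  list(
    nSequences = n,
    completeness = as.list(complCounts),
    fullLength = if (length(fullLens)) list(
      n = length(fullLens), min = min(fullLens),
      median = stats::median(fullLens), max = max(fullLens)) else NULL,
    lengthClasses = as.list(classes),
    repeats = list(min = min(repCounts), max = max(repCounts),
                   lengthHistogram = as.list(table(unitLens))),
    typeFractions = as.list(typeFractions),
    psimFractions = as.list(psimFractions),
    chargedRange = c(min = min(charged), max = max(charged))
  )
}

#' Write a dataset summary report
#'
#' JSON is the canonical machine-readable form; TSV flattens the summary to
#' key/value rows; markdown renders human-readable tables including the
#' type-fraction table.
#'
#' @param summary a summary list from [annotateDataset()].
#' @param path output path.
#' @param fmt "json", "tsv" or "md".
#' @return invisibly, \code{path}.
#' @export
writeReport <- function(summary, path, fmt = c("json", "tsv", "md")) {
  fmt <- match.arg(fmt)
  if (fmt == "json") {
    jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else if (fmt == "tsv") {
    flat <- unlist(summary)
    utils::write.table(
      data.frame(key = names(flat), value = unname(flat)),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- c("# ST dataset summary", "",
               paste("Sequences accepted:", summary$nSequences), "")
    if (!is.null(summary$completeness)) {
      lines <- c(lines, "## Completeness", "",
                 "| call | count |", "|---|---|",
                 vapply(names(summary$completeness), function(k)
                   sprintf("| %s | %s |", k, summary$completeness[[k]]),
                   character(1)), "")
    }
    if (!is.null(summary$typeFractions)) {
      lines <- c(lines, "## Type fractions (%)", "",
                 "| type | percent |", "|---|---|",
                 vapply(names(summary$typeFractions), function(k)
                   sprintf("| %s | %s |", k, summary$typeFractions[[k]]),
                   character(1)), "")
    }
    if (!is.null(summary$psimFractions)) {
      lines <- c(lines, "## Psim fractions among full-length (%)", "",
                 "| threshold | percent |", "|---|---|",
                 vapply(names(summary$psimFractions), function(k)
                   sprintf("| %s | %s |", k, summary$psimFractions[[k]]),
                   character(1)), "")
    }
    writeLines(lines, path)
  }
  invisible(path)
}
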
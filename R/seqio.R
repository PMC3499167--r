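#' Read protein or nucleotide sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] /
#' [Biostrings::readDNAStringSet()] that enforces the dataset conventions
#' used throughout the package: non-empty input, unique identifiers
#' (the token before the first whitespace of each header), uppercase
#' residues, and stop characters (\code{*}) stripped with a warning.
#'
#' @param path path to a FASTA text file.
#' @param kind "protein" or "nucleotide".
#' @return a named character vector of sequences; names are the ids and the
#'   \code{description} attribute keeps the remainder of each header line.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">CarST1 demo", "RKMDFE"), f)
#' readFasta(f)
#' @export
readFasta <- function(path, kind = c("protein", "nucleotide")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- if (kind == "protein") {
    Biostrings::readAAStringSet(path)
  } else {
    Biostrings::readDNAStringSet(path)
  }
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  if (any(grepl("*", seqs, fixed = TRUE))) {
    warning("'*' characters stripped from sequences")
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  if (any(!nzchar(seqs))) stop("empty sequence in ", path)
  names(seqs) <- ids
  attr(seqs, "description") <- setNames(desc, ids)
  attr(seqs, "kind") <- kind
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (or AAStringSet) of sequences;
#'   an optional \code{description} attribute (named character) is appended
#'   to each header.
#' @param path output path.
#' @param wrap line width for sequence lines.
#' @return invisibly, \code{path}.
#' @export
writeFasta <- function(seqs, path, wrap = 60L) {
  if (is(seqs, "XStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(seqs) == 0L) return(invisible(path))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  desc <- attr(seqs, "description")
  for (id in names(seqs)) {
    hdr <- if (!is.null(desc) && !is.na(desc[id]) && nzchar(desc[id])) {
      paste(id, desc[id])
    } else id
    writeLines(paste0(">", hdr), con)
    s <- seqs[[id]]
    starts <- seq.int(1L, nchar(s), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Six-frame translation of a nucleotide sequence
#'
#' Translates a nucleotide sequence in all six reading frames with the
#' standard genetic code. Stops are rendered \code{*}; trailing partial
#' codons are dropped; ambiguous codons (containing N) translate to
#' \code{X}. Frames -1/-2/-3 are the three frames of the reverse
#' complement.
#'
#' @param x a single nucleotide sequence (character or DNAString).
#' @param id identifier used to label the frames.
#' @return named character vector of 6 protein sequences, names
#'   \code{<id>_frame+1} ... \code{<id>_frame-3}.
#' @examples
#' sixFrameTranslate("ATGGATTTT")[["seq_frame+1"]]  # "MDF"
#' @export
sixFrameTranslate <- function(x, id = "seq") {
  s <- toupper(as.character(x))
  if (!grepl("^[ACGTUN]+$", s))
    stop("input is not a nucleotide sequence")
  s <- gsub("U", "T", s, fixed = TRUE)
  fwd <- Biostrings::DNAString(s)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(dna, off) {
    n <- length(dna) - off
    n <- n - n %% 3L
    if (n < 3L) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(dna, start = off + 1L, width = n),
      if.fuzzy.codon = "solve", no.init.codon = TRUE))
  }
  out <- c(
    vapply(0:2, function(o) one(fwd, o), character(1)),
    vapply(0:2, function(o) one(rev, o), character(1))
  )
  names(out) <- paste0(id, "_frame", c("+1", "+2", "+3", "-1", "-2", "-3"))
  out
}

#' Write per-sequence features as GFF3 or TSV
#'
#' Serializes the feature rows of a set of annotations (signal peptide,
#' mature N-terminal region, repeat units, glycosylation sequons,
#' DUF-like domain windows) with 1-based inclusive residue coordinates.
#' The GFF3 \code{source} column is "repeatst" and the seqid is the protein
#' identifier.
#'
#' @param annotations a list of [STAnnotation-class] objects (or a single
#'   one).
#' @param path output path.
#' @param fmt "gff3" or "tsv".
#' @return invisibly, the feature data.frame that was written.
#' @export
writeFeatureTable <- function(annotations, path, fmt = c("gff3", "tsv")) {
  fmt <- match.arg(fmt)
  if (is(annotations, "STAnnotation")) annotations <- list(annotations)
  feats <- do.call(rbind, lapply(annotations, featureRows))
  if (is.null(feats))
    feats <- data.frame(seq_id = character(), feature_kind = character(),
                        start = integer(), end = integer(),
                        attributes = character())
  if (fmt == "tsv") {
    utils::write.table(feats, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    if (nrow(feats)) {
      lines <- sprintf("%s\trepeatst\t%s\t%d\t%d\t.\t.\t.\t%s",
                       feats$seq_id, feats$feature_kind,
                       feats$start, feats$end, feats$attributes)
      writeLines(lines, con)
    }
  }
  invisible(feats)
}

# flatten one STAnnotation into FeatureRow records
featureRows <- function(ann) {
  stopifnot(is(ann, "STAnnotation"))
  if (!ann@accepted) return(NULL)
  rows <- list()
  n <- nchar(ann@residues)
  cl <- ann@cleavageAfter
  if (!is.na(cl)) {
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = ann@seqId, feature_kind = "signal_peptide",
      start = 1L, end = cl,
      attributes = paste0("ID=", ann@seqId, ":sp;confidence=",
                          ann@signalConfidence))
  }
  u <- ann@region@units
  firstRep <- min(u$start)
  if (!is.na(cl) && firstRep > cl + 1L) {
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = ann@seqId, feature_kind = "nterm_region",
      start = cl + 1L, end = firstRep - 1L,
      attributes = paste0("ID=", ann@seqId, ":nterm"))
  }
  for (i in seq_len(nrow(u))) {
    kind <- if (u$status[i] == "truncated_terminal") "truncated_repeat"
            else "repeat"
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = ann@seqId, feature_kind = kind,
      start = u$start[i], end = u$end[i],
      attributes = paste0("ID=", ann@seqId, ":rep", u$index[i],
                          ";x4=", u$x4[i], ";status=", u$status[i]))
  }
  g <- ann@glycoSites
  for (i in seq_len(nrow(g))) {
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = ann@seqId, feature_kind = "glyco_site",
      start = g$position[i], end = g$position[i] + 2L,
      attributes = paste0("ID=", ann@seqId, ":glyc", i,
                          ";sequon=", g$sequon[i]))
  }
  duf <- countDufLikeDomains(ann@region)
  if (duf[["complete"]] > 0L) {
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = ann@seqId, feature_kind = "duf_like_domain",
      start = firstRep, end = max(u$end),
      attributes = paste0("ID=", ann@seqId, ":duf;complete=",
                          duf[["complete"]], ";truncated=",
                          duf[["truncated"]]))
  }
  out <- do.call(rbind, rows)
  stopifnot(all(out$start >= 1L), all(out$end <= n),
            all(out$start <= out$end))
  out
}
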
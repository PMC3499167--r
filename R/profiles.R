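#' Position profile and information content of anchored repeats
#'
#' Builds per-column residue counts, frequencies and information content
#' (in bits) for a set of equal-length repeat units anchored at position 1,
#' as in a sequence logo. The information content of column i is
#' \code{log2(20) - H_i} with \code{H_i = -sum f log2 f} over the observed
#' residue frequencies; no small-sample correction is applied, so a fully
#' conserved column scores log2(20) = 4.32 bits and a uniform column 0.
#'
#' @param repeats character vector (or AAStringSet) of >= 2 equal-length
#'   repeat sequences; callers typically select the 25- or 26-aa subsets.
#' @return list of class \code{ProfileMatrix}: \code{counts} and
#'   \code{freqs} (residue x position matrices) and \code{bits}
#'   (numeric per position).
#' @examples
#' p <- buildProfile(rep("DFEPRPNVSAY", 10))
#' round(p$bits[1], 2)  # 4.32
#' @export
buildProfile <- function(repeats) {
  if (is(repeats, "XStringSet")) repeats <- as.character(repeats)
  repeats <- toupper(repeats)
  if (length(repeats) < 2L) stop("need >= 2 repeats")
  if (length(unique(nchar(repeats))) != 1L)
    stop("repeats must have equal length")
  counts <- Biostrings::consensusMatrix(Biostrings::AAStringSet(repeats))
  counts <- counts[rownames(counts) %in% AA20, , drop = FALSE]
  freqs <- sweep(counts, 2L, colSums(counts), "/")
  bits <- apply(freqs, 2L, function(f) {
    f <- f[f > 0]
    log2(20) + sum(f * log2(f))
  })
  structure(list(counts = counts, freqs = freqs, bits = unname(bits)),
            class = "ProfileMatrix")
}

#' @export
print.ProfileMatrix <- function(x, ...) {
  cat("ProfileMatrix:", ncol(x$counts), "columns,",
      sum(x$counts[, 1L]), "sequences\n")
  cat("bits:", paste(round(x$bits, 2), collapse = " "), "\n")
  invisible(x)
}

#' Two-group residue enrichment (two-sample logo)
#'
#' Compares per-column residue frequencies between two groups of
#' equal-length anchored repeats, as in a two-sample logo. For each column
#' and residue observed in either group, the frequency difference
#' \code{f_A - f_B} is tested with a two-sided Fisher exact test on the
#' 2x2 count table; residues passing \code{alpha} are reported as enriched
#' (positive difference, group A preference) or depleted. Positions fully
#' conserved in both groups never appear (difference 0). No multiplicity
#' correction is applied, matching the tool's convention.
#'
#' @param groupA,groupB character vectors of equal-length repeats.
#' @param alpha significance threshold.
#' @return data.frame: \code{position}, \code{residue}, \code{dfreq},
#'   \code{p}, \code{direction} ("enriched"/"depleted" from group A's
#'   viewpoint).
#' @export
twoSampleLogo <- function(groupA, groupB, alpha = 0.05) {
  if (is(groupA, "XStringSet")) groupA <- as.character(groupA)
  if (is(groupB, "XStringSet")) groupB <- as.character(groupB)
  groupA <- toupper(groupA); groupB <- toupper(groupB)
  if (!length(groupA) || !length(groupB))
    stop("both groups must be non-empty")
  L <- unique(nchar(c(groupA, groupB)))
  if (length(L) != 1L)
    stop("all repeats must have the same length across both groups")
  nA <- length(groupA); nB <- length(groupB)
  rows <- list()
  for (j in seq_len(L)) {
    resA <- substring(groupA, j, j)
    resB <- substring(groupB, j, j)
    for (r in unique(c(resA, resB))) {
      a <- sum(resA == r); b <- sum(resB == r)
      df <- a / nA - b / nB
      if (df == 0) next
      p <- stats::fisher.test(matrix(c(a, nA - a, b, nB - b), 2L))$p.value
      if (p <= alpha) {
        rows[[length(rows) + 1L]] <- data.frame(
          position = j, residue = r, dfreq = df, p = p,
          direction = if (df > 0) "enriched" else "depleted")
      }
    }
  }
  if (!length(rows))
    return(data.frame(position = integer(0), residue = character(0),
                      dfreq = numeric(0), p = numeric(0),
                      direction = character(0)))
  do.call(rbind, rows)
}
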
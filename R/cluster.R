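# identity scoring matrix over the protein alphabet (match +1, mismatch 0)
.identityMatrix <- function() {
  letters <- c(AA20, "X", "B", "Z", "J", "U", "O", "*", "-", "+")
  m <- matrix(0L, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 1L
  m
}

#' Identity distance from a global pairwise alignment
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and linear
#' gap penalty -1, followed by distance = 1 - identities / alignment length
#' (gapped columns included in the length). This is the guide-distance
#' stand-in used for family-level clustering.
#'
#' @param a,b protein sequences.
#' @return distance in [0, 1].
#' @examples
#' pairwiseDistance("AAAA", "AATA")  # 0.25
#' @export
pairwiseDistance <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nchar(a) || !nchar(b)) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(a), Biostrings::AAStringSet(b),
    substitutionMatrix = .identityMatrix(),
    gapOpening = 0, gapExtension = 1, type = "global")
  alnLen <- nchar(as.character(Biostrings::pattern(pa)))
  1 - Biostrings::nmatch(pa) / alnLen
}

#' All-pairs distance matrix
#'
#' @param seqs named character vector (or AAStringSet) of sequences.
#' @return symmetric numeric matrix with zero diagonal and the sequence
#'   names as labels.
#' @export
distanceMatrix <- function(seqs) {
  if (is(seqs, "XStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  n <- length(seqs)
  stopifnot(n >= 2L, !is.null(names(seqs)))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- pairwiseDistance(seqs[[i]], seqs[[j]])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining (via \pkg{ape}); input must be a
#' symmetric matrix with zero diagonal and >= 3 labels.
#'
#' @param d symmetric distance matrix with labels.
#' @return an \code{ape::phylo} tree.
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need >= 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-12))
    stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("diagonal must be zero")
  if (is.null(rownames(d))) stop("matrix must carry labels")
  ape::nj(d)
}

#' Identity distance between rows of an alignment matrix
#'
#' @param mat character matrix, rows = taxa, columns = aligned positions.
#' @return symmetric distance matrix (fraction of differing columns).
#' @export
identityDistance <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- mean(mat[i, ] != mat[j, ])
    }
  }
  d
}

#' Anchored repeat alignment for a set of annotated sequences
#'
#' Builds the equal-length alignment used for bootstrap resampling: for
#' each sequence, the first canonical repeat unit of the dataset-wide modal
#' length (sequences without such a unit are dropped with a warning).
#'
#' @param annotations list of [STAnnotation-class] objects.
#' @return character matrix, rows = sequences, columns = unit positions.
#' @export
repeatAlignment <- function(annotations) {
  annotations <- Filter(function(a) a@accepted, annotations)
  allLens <- unlist(lapply(annotations, function(a) {
    u <- a@region@units
    u$length[u$status == "canonical"]
  }))
  modal <- .modalLength(allLens)
  rows <- list()
  for (a in annotations) {
    u <- a@region@units
    hit <- which(u$status == "canonical" & u$length == modal)
    if (!length(hit)) {
      warning("no canonical unit of modal length in ", a@seqId,
              "; dropped from alignment")
      next
    }
    rows[[a@seqId]] <- .chars(u$seq[hit[1L]])
  }
  do.call(rbind, rows)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Columns of the anchored repeat alignment are resampled with replacement;
#' each replicate yields an identity-distance matrix and an NJ tree, and
#' the support of each internal edge is the percentage of replicates
#' containing its bipartition. Fixed seeds give bit-reproducible supports.
#'
#' @param mat character alignment matrix (rows = taxa), e.g. from
#'   [repeatAlignment()].
#' @param nReplicates number of bootstrap replicates (the family analysis
#'   convention is 2000).
#' @param seed RNG seed.
#' @return an \code{ape::phylo} tree; \code{node.label} holds the percent
#'   supports (NA for the root node label).
#' @export
bootstrapSupport <- function(mat, nReplicates = 2000L, seed = 1L) {
  nReplicates <- as.integer(nReplicates)
  if (nReplicates < 1L) stop("nReplicates must be >= 1")
  stopifnot(is.matrix(mat), nrow(mat) >= 3L)
  tree <- njTree(identityDistance(mat))
  set.seed(as.integer(seed))
  reps <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    reps[[r]] <- njTree(identityDistance(mat[, cols, drop = FALSE]))
  }
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tree$node.label <- round(100 * counts / nReplicates, 1)
  tree
}

#' Write a PHYLIP-style square distance matrix
#'
#' @param d symmetric distance matrix with labels.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writePhylip <- function(d, path) {
  d <- as.matrix(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste0(formatC(rownames(d)[i], width = -10),
                      paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  }
  invisible(path)
}
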
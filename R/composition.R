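# average residue masses (Da); peptide MW adds one water
AA_MASS_AVG <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                 C = 103.1388, Q = 128.1307, E = 129.1155, G = 57.0519,
                 H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                 M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
                 T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01528

# EMBOSS pKa set used for the isoelectric point
PKA_EMBOSS <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
                H = 6.5, K = 10.8, R = 12.5, Y = 10.1)

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water; undefined residues (X)
#' are ignored.
#'
#' @param residues protein sequence.
#' @return mass in daltons.
#' @export
molecularWeight <- function(residues) {
  ch <- .chars(toupper(as.character(residues)))
  sum(AA_MASS_AVG[ch], na.rm = TRUE) + WATER_MASS
}

#' Isoelectric point by bisection on the net-charge curve
#'
#' Net charge Q(pH) is the Henderson-Hasselbalch sum over the N-terminus,
#' C-terminus and the ionizable side chains (D, E, C, Y negative; H, K, R
#' positive) with the EMBOSS pKa set. Q is strictly decreasing in pH, so
#' the root is unique; bisection on [0, 14] runs until |Q| < 1e-4.
#'
#' @param residues protein sequence.
#' @param tol convergence tolerance on |Q|.
#' @return the pI (pH at which Q = 0).
#' @export
isoelectricPoint <- function(residues, tol = 1e-4) {
  ch <- .chars(toupper(as.character(residues)))
  cnt <- c(C = sum(ch == "C"), D = sum(ch == "D"), E = sum(ch == "E"),
           H = sum(ch == "H"), K = sum(ch == "K"), R = sum(ch == "R"),
           Y = sum(ch == "Y"))
  q <- function(pH) {
    pos <- 1 / (1 + 10^(pH - PKA_EMBOSS["Nterm"])) +
      cnt["H"] / (1 + 10^(pH - PKA_EMBOSS["H"])) +
      cnt["K"] / (1 + 10^(pH - PKA_EMBOSS["K"])) +
      cnt["R"] / (1 + 10^(pH - PKA_EMBOSS["R"]))
    neg <- 1 / (1 + 10^(PKA_EMBOSS["Cterm"] - pH)) +
      cnt["C"] / (1 + 10^(PKA_EMBOSS["C"] - pH)) +
      cnt["D"] / (1 + 10^(PKA_EMBOSS["D"] - pH)) +
      cnt["E"] / (1 + 10^(PKA_EMBOSS["E"] - pH)) +
      cnt["Y"] / (1 + 10^(PKA_EMBOSS["Y"] - pH))
    unname(pos - neg)
  }
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    qm <- q(mid)
    if (abs(qm) < tol) return(mid)
    if (qm > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Kyte-Doolittle hydropathy profile
#'
#' Centered sliding-window mean of Kyte-Doolittle hydropathy values; the
#' (window-1)/2 positions at each end are trimmed. Also returns the grand
#' mean over all residues (GRAVY).
#'
#' @param residues protein sequence.
#' @param window odd window size, <= sequence length.
#' @return list with \code{profile} (numeric, length n - window + 1) and
#'   \code{gravy}.
#' @export
hydropathyProfile <- function(residues, window = 9L) {
  s <- toupper(as.character(residues))
  n <- nchar(s)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window > n) stop("window longer than sequence")
  v <- .kd(.chars(s))
  prof <- as.numeric(stats::filter(v, rep(1 / window, window), sides = 2))
  half <- (window - 1L) %/% 2L
  prof <- prof[(half + 1L):(n - half)]
  list(profile = prof, gravy = mean(v))
}

#' Composition report for a mature ST protein
#'
#' Descriptive statistics used throughout the family characterization:
#' length, average molecular weight, pI, the charged-residue fraction over
#' the set {D,E,K,R,H,Y,C} (the family's definition of charged residues),
#' acidic (DE) and basic (KRH) fractions, per-residue fractions, counts of
#' the structurally notable residues (G, P, Y, C, W) and the hydropathy
#' profile. Undefined residues (X) are excluded from the denominators of
#' the class fractions.
#'
#' @param residues mature protein sequence.
#' @param window hydropathy window (profile omitted for shorter sequences).
#' @return list of class \code{CompositionReport}.
#' @export
compositionReport <- function(residues, window = 9L) {
  s <- toupper(as.character(residues))
  if (!nchar(s)) stop("empty sequence")
  ch <- .chars(s)
  defined <- ch[ch %in% AA20]
  nd <- length(defined)
  frac <- function(set) if (nd) sum(defined %in% set) / nd else NA_real_
  perResidue <- vapply(AA20, function(a) frac(a), numeric(1))
  hyd <- if (nchar(s) >= window) hydropathyProfile(s, window) else
    list(profile = numeric(0), gravy = mean(.kd(ch)))
  structure(list(
    length = nchar(s),
    mwDa = molecularWeight(s),
    pi = isoelectricPoint(s),
    fracCharged = frac(c("D", "E", "K", "R", "H", "Y", "C")),
    fracAcidic = frac(c("D", "E")),
    fracBasic = frac(c("K", "R", "H")),
    perResidue = perResidue,
    counts = c(G = sum(ch == "G"), P = sum(ch == "P"), Y = sum(ch == "Y"),
               C = sum(ch == "C"), W = sum(ch == "W")),
    hydropathy = hyd$profile,
    gravy = hyd$gravy
  ), class = "CompositionReport")
}

#' @export
print.CompositionReport <- function(x, ...) {
  cat(sprintf(
    "CompositionReport: %d aa, %.1f kDa, pI %.2f, charged %.1f%% (acidic %.1f%%, basic %.1f%%), GRAVY %.2f\n",
    x$length, x$mwDa / 1000, x$pi, 100 * x$fracCharged,
    100 * x$fracAcidic, 100 * x$fracBasic, x$gravy))
  invisible(x)
}
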
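---
title: "Annotating ST tandem-repeat proteins: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating ST tandem-repeat proteins: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatST)
```

## The protein model

ST proteins are secreted plant proteins organized as three segments:

1. a **signal peptide** of 19–28 residues (most often 22), with the
   hydrophobic core typical of secretory proteins;
2. a **mature N-terminal region** of roughly 30–80 residues that starts
   with Arg (usually Arg-Lys), carries a Tyr-Trp dyad at mature positions
   7–8 (one residue later in a small minority), and the single Cys of the
   mature protein;
3. a **tandem-repeat region** whose units each begin with the hexapeptide
   `[DE]FEPRP`, followed by four partially conserved residues (X4) and a
   fully conserved Tyr at unit position 11. The modal unit is 25 or 26
   residues, with a D/N-rich stretch after the Tyr and a K-rich tail block
   (consensus `DFEPRP X4 Y X6-7 KXKKXFXK`). The region typically ends with
   a truncated unit of about 13 residues, so full-length sequences end
   with Tyr followed by two or three residues.

Everything in the package is a consequence of this model: the signature
defines family membership, the anchors define segmentation, the X4 defines
the type system, and the terminal features define completeness.

## Detection and segmentation

`scanMotif()` reports each anchor: an exact `[DE]FEPRP` (optionally with
at most one mismatch, for callers that want a fuzzy scan) followed by a
Tyr at offset 11. The Tyr requirement is never relaxed: the family
definition says "similar to" the signature without quantifying similarity,
so the package operationalizes it as *exact hexapeptide + exact Tyr* by
default and exposes the single-mismatch option for imperfect leading
repeats only. Overlapping candidates (closer than the 11-residue
signature) are resolved leftmost-first; with the exact scan this situation
cannot arise, but the rule keeps the fuzzy scan deterministic.

`segmentRepeats()` implements the family's segmentation convention: each
anchor starts a new unit, unit *k* extends to the residue before anchor
*k+1*, and the last unit runs to the C-terminus. Decisions behind the
edge cases:

* **Modal length** is the most frequent length among units with both
  boundaries anchored, ties resolved to the smaller length (a fixed,
  data-independent tie-break).
* **Truncated flag.** The last unit is `truncated_terminal` when shorter
  than the modal length. With a single anchor there is no mode to compare
  against; the unit is then called truncated when shorter than 22
  residues, the lower bound of regular repeat lengths in this family.
  This keeps a lone 13-residue terminal unit correctly flagged while a
  lone full unit stays canonical.
* **Imperfect leading repeats.** Families often start with one or two
  degenerate units. A pre-scan with one hexapeptide mismatch (Tyr still
  required) covers at most two modal lengths upstream of the first exact
  anchor and adds `imperfect_leading` units. Restricting the window keeps
  false leading units out of long hydrophilic N-terminal regions.
* **Repeat counts include the truncated terminal unit**, following the
  family convention that every signature occurrence starts a unit,
  including the last truncated one.
* **Length pattern** is `uniform` when all regular units share one
  length, `alternating` when exactly two lengths strictly alternate, and
  `heterogeneous` otherwise.

Coordinates are 1-based inclusive everywhere — in R objects and in the
GFF3/TSV output. Keeping a single convention in an R package avoids the
off-by-one traffic that a mixed 0-based internal representation would
invite in this language.

## Repeat perfection (Psim)

The original perfection score comes from an external repeat-detection
program whose internals are not reproducible from its published
description, so the package defines the score explicitly: anchor all
units at position 1; in every column take the plain-majority residue
(frequency ties resolved in favour of the earliest unit); Psim is the
fraction of unit positions equal to their column consensus, with the
truncated unit compared over its own length only. The score is 1 exactly
when all units agree over their compared spans, and the conventional
reading holds: values of 0.7 and above indicate perfect or nearly perfect
repeats. Because the definition differs from the external program's,
agreement with published Psim fractions is treated as qualitative; the
test suite checks the package's own definition against a brute-force
oracle instead.

`deriveConsensus()` uses the same column machinery with a frequency
threshold (default 0.5, the smallest value at which a reported residue is
a true majority or exactly half); columns below threshold print `X`.

## Maturation heuristic

Signal-peptide prediction tools are not reimplemented. The stand-in
heuristic relies on two family facts: the mature protein starts with Arg
in nearly all sequences, and signal peptides have hydrophobic cores.
Candidate cleavage points 19–28 are scanned; the first whose next residue
is Arg and whose core window (positions 6 to candidate−4) has mean
Kyte–Doolittle hydropathy above 1.0 is accepted with high confidence.
The 1.0 threshold sits well above the hydropathy of the hydrophilic
mature regions (around −2) and well below genuine cores (around +3), so
the margin is wide on both sides; it is configurable. Without an
Arg-anchored candidate the highest-hydropathy candidate is used and
flagged low-confidence; if even that core is not hydrophobic, no signal
peptide is called (with a warning). Externally determined cleavage sites
can be supplied per sequence via a TSV sidecar and are used verbatim.

Completeness composes terminal rules: N-complete needs a stop codon
before the first Met (nucleotide mode) *or* a signal peptide plus the
mature Tyr-Trp dyad; C-complete needs a terminal stop without a detected
frameshift *or* Tyr at position −3 or −4 (the truncated-unit ending).
The published description of the dyad window ("26–30 from the first
methionine") is ambiguous between codon and residue counting; the package
reads it as a residue window implied by the modal 22-residue signal
peptide plus mature positions 7–8, and scans mature positions 7–9 so the
known one-residue offset cases are admitted and flagged. Neither reading
is asserted in tests. Without a signal peptide the dyad cannot support
N-completeness (it is a mature-coordinate feature), which keeps
N-terminally clipped fragments from being over-called.

## Typing and glycosylation

The X4 type system is driven by unit positions 7 and 9: Ser at 7 is type
I; Asn at 7 with Ser/Thr at 9 is IIa (this is exactly what makes the
N-glycosylation sequon `N-{P}-[ST]-{P}`); Asn at 7 with Phe/Leu at 9 is
IIb; Asp/Thr at 7 is III. Position 9 rather than a full 4-mer regular
expression performs the IIa/IIb discrimination because the sequon logic
is what distinguishes the subtypes. The protein-level call is a strict
majority (> 0.5) over canonical units — "predominant" is not quantified
in the family literature, and a strict majority is the weakest
order-invariant reading; anything at or below half is reported `mixed`
with components by share. Truncated terminal units are excluded from the
vote (their X4 may be missing), as are imperfect leading units.

Sequon detection reports all (including overlapping) matches of
`N-{P}-[ST]-{P}`, with the trailing exclusion applied only when a
following residue exists.

## Profiles and two-group comparison

`buildProfile()` computes per-column counts, frequencies and information
content `log2(20) − H` over equal-length anchored units, without a
small-sample correction — a unanimous column scores 4.32 bits, a uniform
one 0. Zero frequencies contribute zero to the entropy and no
pseudocounts are added, so the values reproduce the standard logo
convention. `twoSampleLogo()` tests each column/residue with a two-sided
Fisher exact test on the 2x2 count table (counts here are small, so an
exact test needs no variance assumptions), reporting residues passing
alpha = 0.05 split into enriched and depleted; no multiplicity correction
is applied by default, matching the convention of the graphical tool this
mirrors. Positions with equal frequencies in both groups (including fully
conserved shared positions such as Pro-6 and Tyr-11) can never appear.

## Composition

The charged-residue fraction uses the family's own definition of charged
residues, the set {D,E,K,R,H,Y,C}; undefined residues (X) are excluded
from denominators. pI solves the Henderson–Hasselbalch net-charge
equation by bisection on pH in [0, 14] to |Q| < 1e-4 (the charge curve is
strictly decreasing, so the root is unique) under the EMBOSS pKa set
(N-term 8.6, C-term 3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5,
Y 10.1). The program originally used for the family's pI values has a
proprietary pKa table, so exact parity with published pI ranges is not
asserted — published acidity is treated as a qualitative expectation.
Molecular weight uses average residue masses plus one water. Hydropathy
is the centered Kyte–Doolittle window mean (default window 9, odd
windows only, trimmed ends), plus the grand mean (GRAVY).

## Clustering

Family-level clustering needs distances, not alignments, so the package
uses global pairwise alignment (match +1, mismatch 0, linear gap −1) and
the identity distance 1 − identities/alignment-length instead of a full
multiple-alignment reimplementation. Trees are canonical neighbor
joining. Bootstrap resamples columns of the anchored repeat-region
alignment (one modal-length canonical unit per sequence) rather than raw
unaligned sequences — the repeat alignment is the only positionally
homologous, equal-length material available without an MSA; supports are
the percentage of replicates containing each internal bipartition, and a
fixed seed makes them bit-reproducible. The conventional replicate count
for this family's analyses is 2000; tests use far fewer since they check
reproducibility and clade recovery, not support calibration.

## The synthetic generator

`generateST()` emulates the family model exactly as stated above; its
defaults are the study conditions (22-aa signal, 55-aa N-terminal
region, six 25-aa repeats, 13-aa truncated terminal unit, no noise).
Residue pools are chosen so the mature region reproduces the family's
composition claims: hydrophilic throughout (the filler alphabet has mean
hydropathy around −2), acidic overall (D/E outweigh K/R/H, giving pI
values in the low-4 range), with the X6-7 stretch D/N-rich and the tail
block K-rich per the repeat consensus. Cys, Trp, Tyr, Met and Arg are
excluded from filler so each designated feature position (single Cys,
single Trp, anchor Tyr, initial Met, mature Arg) is unique by
construction — which is what makes ground-truth recovery exact rather
than probabilistic. Substitution noise never introduces Cys or Trp, and
anchor positions (hexapeptide + Tyr-11) are protected by default so that
noise studies perturb repeat bodies, not the signature.

Fragment modes cut the precursor so that each completeness call is forced
by construction: `n_only` cuts inside the last unit's hexapeptide (no
terminal Tyr pattern), `c_only` and `internal` drop the Met, signal and
dyad. Decoys implement the repeat grammars of the cell-wall protein
classes used as negative controls — P-rich motifs (PRP), Ser-Pro4
pentapeptides with Hyp written as plain P (HRGP), (Gly-X)n with Gly
fraction above 0.4 (GRP), Ala/Ser/Thr-Pro glycomodules (AGP) — plus a
residue-preserving shuffle, rejection-resampled so no decoy carries the
signature. `generateFamily()` derives species members from per-clade base
sequences with protected feature positions, so clades are recoverable by
clustering at zero noise by construction.

`generateCuratedSet()` is a **synthetic stand-in** for the family's
curated sequence collection, which is not redistributable with the
package. It designs 136 sequences to the published marginals (72
full-length, 38 N-complete, 7 C-complete, 19 internal; full-length
lengths 103–493 with ~36/41/23% size classes; repeat counts 2–17; 21%
type I, 55% IIa, 2% IIb, 13% III, the rest mixed) and lets the pipeline
recompute those statistics by rule. Passing that check demonstrates that
the annotation rules recover designed truth on model-faithful input — it
does **not** validate the rules against the real curated sequences, nor
against features the generator does not emulate: double-Tyr repeats,
species-specific hexapeptide drift beyond one mismatch, sequencing
errors, frameshifts, or N-terminal regions outside the 30–80 residue
band.

## Problem sizes and determinism

The test suite runs desk-scale: 200 seeded noise-free recoveries across
the full parameter ranges, 60 sequences at 5% substitution noise, 1000
decoys, exhaustive 2–4-unit Psim oracle sets (336 regions), 30 additive
quartets per topology, and bootstrap reproducibility at 100–200
replicates — about half a minute in total. All randomness is seeded;
`generateST()` and friends call `set.seed()` internally so a config is a
complete recipe for its sequence.

## Known limitations

* The maturation heuristic is rule-based; probabilistic signal-peptide
  scoring and subcellular targeting are out of scope (external predictions
  can be supplied via the sidecar).
* The DUF-domain count is a windowing proxy over repeat units, not a
  domain-database reproduction.
* Psim is this package's explicit re-definition; published fractions from
  the external program are comparable only qualitatively.
* Clustering uses pairwise identity distances; no multiple alignment or
  likelihood trees.
* Six-frame translation assumes the standard genetic code; ambiguous
  codons translate to X.
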
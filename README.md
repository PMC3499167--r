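# repeatST

Detection, annotation and classification of plant **ST ("ShooT specific")
tandem-repeat proteins** in protein sequences.

ST proteins are a family of secreted plant proteins restricted to a few
dicotyledonous families (mainly Fabaceae and Asteraceae). Their hallmark is
a C-terminal region of tandem repeats of 22–27 residues, each beginning
with the hexapeptide **(D/E)FEPRP**, followed by four partially conserved
residues (**X₄**) and a fully conserved tyrosine at repeat position 11:

```
repeat unit:   [DE] F E P R P  X X X X  Y   (tail, modal 25/26 aa)
position:        1  2 3 4 5 6  7 8 9 10 11  12 ... 25/26
```

Upstream of the repeats lie a signal peptide (19–28 aa, modal cleavage
22/23) and a mature N-terminal region that starts with Arg, carries a
Tyr-Trp dyad near mature positions 7–8 and the single Cys of the mature
protein. The repeat region typically ends with a truncated unit of about
13 aa. The X₄ pattern defines the family's types: **I** (SxTx, no
N-glycosylation sequon), **IIa** (NxSx, one sequon per repeat), **IIb**
(Nx(F/L)x) and **III** (DxT/Sx).

The package is aimed at anyone characterizing this family (or screening
candidate sequences for it): it detects the signature, segments and
profiles the repeats, delineates the mature protein, classifies
completeness and type, and clusters family members.

## What it computes

* **Signature scan and segmentation** — every anchor position of
  `[DE]FEPRP-X4-Y` starts a new repeat unit, including the final truncated
  one (`scanMotif()`, `segmentRepeats()`).
* **Repeat perfection (Psim)** — the fraction of unit positions matching
  the column-majority consensus of the anchored repeat alignment; 1.0 for
  perfect repeats, ≥ 0.7 for nearly perfect ones (`psimScore()`).
* **Consensus and logos** — majority consensus per column
  (`deriveConsensus()`), information content in bits with a 4.32-bit
  maximum (`buildProfile()`), and two-group residue enrichment by Fisher
  exact test (`twoSampleLogo()`).
* **Maturation** — Arg-anchored hydropathy heuristic for the signal
  peptide cleavage site (or user-supplied sites), mature N-terminal
  features, and completeness calls (full / N-complete / C-complete /
  internal) from the terminal rules (`predictMatureStart()`,
  `ntermFeatures()`, `classifyCompleteness()`).
* **Typing and glycosylation** — PROSITE PS00001 sequons
  (`nglycSites()`), per-repeat X₄ categories and strict-majority type
  calls (`x4Category()`, `classifyProtein()`), ST1/ST2… family naming
  (`assignFamilyNames()`).
* **Composition** — charged fraction over the family's DEKRHYC set,
  pI by bisection (EMBOSS pKa set), average molecular weight,
  Kyte–Doolittle hydropathy (`compositionReport()`).
* **Clustering** — identity distances from global alignment, neighbor
  joining and column-bootstrap supports (`pairwiseDistance()`,
  `njTree()`, `bootstrapSupport()`).
* **Synthetic data** — seeded, ground-truthed generators for ST
  precursors, fragments, multi-species families and cell-wall-protein
  decoys (PRP/HRGP/GRP/AGP/shuffle) (`generateST()`, `generateDecoy()`,
  `generateFamily()`, `generateCuratedSet()`).

## Worked example

```r
library(repeatST)

rec <- generateST(stConfig(seed = 7))      # a ground-truthed precursor
ann <- annotateSequence(rec$residues, id = "SynST1")
ann
#> STAnnotation for SynST1 ( 215 aa )
#>   signal peptide: cleavage after 22 ( high )
#>   repeats: 6  type: IIa  completeness: full
#>   Psim: 0.7609  N-glyc sites: 8

repeatUnits(ann)[, c("index", "start", "end", "length", "x4", "status")]
#>   index start end length   x4             status
#> 1     1    78 102     25 NASI          canonical
#> 2     2   103 127     25 NVSI          canonical
#> 3     3   128 152     25 NVSA          canonical
#> 4     4   153 177     25 NISA          canonical
#> 5     5   178 202     25 NVSA          canonical
#> 6     6   203 215     13 NVSA truncated_terminal

consensusSeq(repeatRegion(ann))
#> "DFEPRPNVSAYXXXXXDKXKKXFXK"
```

Reading the output: the 215-aa precursor cleaves after residue 22 (the
modal signal-peptide length), six repeat units follow the 77-residue
N-terminal region, each 25 aa and anchored `DFEPRP…Y`, the last truncated
to 13 aa. Every unit carries the type-IIa `NxSx` pattern, creating one
N-glycosylation sequon per repeat (8 sites overall). Psim 0.76 marks the
repeats as nearly perfect; the consensus shows the conserved anchor,
X₄, tyrosine and the K-rich tail block with `X` at unconserved columns.
The mature region is hydrophilic and acidic (GRAVY −1.93, pI 4.02),
as expected for the family.

Dataset-level work goes through `annotateDataset()`, which returns
per-sequence annotations plus a summary (completeness counts, size
classes, repeat statistics, type fractions, Psim fractions), and
`writeFeatureTable()` / `writeReport()` for GFF3/TSV/JSON/markdown
output. A thin command-line wrapper with `annotate`, `simulate` and
`tree` subcommands is installed at `inst/exec/repeatst`.

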
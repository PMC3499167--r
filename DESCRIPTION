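Package: repeatST
Title: Detection, Annotation and Classification of Plant ST Tandem-Repeat Proteins
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to detect the (D/E)FEPRP-X4-Tyr tandem-repeat signature of
    plant ShooT-specific (ST) proteins in protein sequences, segment and
    profile the repeat region, delineate the signal peptide and mature
    N-terminal features, classify sequences into ST types I/IIa/IIb/III via
    the X4 pattern and its N-glycosylation sequon, score repeat perfection
    (Psim), compute sequence-logo information content and two-group residue
    enrichment, and cluster family members with neighbor-joining trees and
    bootstrap support. Includes a ground-truthed synthetic-sequence generator
    with cell-wall-protein decoy families (PRP, HRGP, GRP, AGP) for
    validation, and a pipeline that annotates a FASTA dataset and emits
    summary statistics and feature tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
biocViews: SequenceMatching, Annotation, Classification, Phylogenetics
RoxygenNote: 7.3.3
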
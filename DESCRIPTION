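Package: ChargedRegions
Title: Detection, Scoring, Structure and Conservation of Highly Charged
    Protein Regions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Proteome-scale analysis of highly charged protein regions.
    Detects compositionally enriched regions with a triangular-weighted
    sliding window; scores regions for charge content (FCR, NCPR), Das-Pappu
    charge patterning (kappa), Kyte-Doolittle hydropathy and compositional
    (Shannon) complexity; ingests per-residue secondary-structure and
    confidence tracks and classifies residues and regions as helical,
    disordered or intermediate; trains a composition-only logistic
    classifier separating helical from disordered regions and compares it
    with the charge/hydropathy (Uversky) heuristic; and quantifies
    evolutionary conservation of compositional enrichment across multiple
    sequence alignments, including a compositional-drift score over sets of
    four amino acids. A synthetic-data module generates proteomes, ORFs,
    structure tracks and evolved alignments with known ground truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    glmnet,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Sequencing, Proteomics, Classification, Alignment,
    StructuralPrediction
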
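Package: raftCRAC
Title: CRAC Motif Scanning and Lipid-Raft Localization Analysis for Membrane Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the association of transmembrane ion channels with
    cholesterol-rich membrane domains. Implements a variable-gap scanner for
    CRAC (Cholesterol Recognition/interaction Amino acid Consensus) motifs
    restricted to transmembrane segments and their flanking stretches,
    property-class conservation and consensus scoring of ortholog alignments,
    quantification of density-gradient partition profiles and their shift
    under cholesterol depletion, spot detection/tracking and a co-movement
    colocalization score for two-channel TIRF time series, membrane-versus-cell
    reporter quantification from confocal images, and Hill-model dose-response
    fitting with bootstrap condition comparison. Ground-truthed synthetic data
    generators make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    IRanges,
    EBImage,
    minpack.lm,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, SequenceMatching, Alignment, CellBiology, Visualization
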
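Package: degronCTS
Title: Differential CTCF Occupancy, Motif Clustering and Loop
    Quantification for Acute-Depletion Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing acute transcription-factor depletion
    experiments built around CTCF degron time courses: reproducible
    Cut&Run peak consensus across clonal replicates called at two FDR
    confidence levels, blacklist filtering, FPKM quantification and
    reduced/retained/gained occupancy classification; clustering of CTCF
    motifs at 40-bp linkage into 1X/2X/3X target-site (CTS) classes with
    rank-sum comparisons of binding loss between classes; genomic feature
    annotation with promoter distance bins; probe-normalised Capture-C
    interaction quantification over defined loop windows; and integration
    of differential-expression tables with loop-disrupted and
    enhancer-docking gene sets.  A synthetic-data generator with planted
    ground truth (CTS orders, occupancy effects, loop multipliers, DEG
    membership) makes every stage testable end-to-end without external
    sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
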
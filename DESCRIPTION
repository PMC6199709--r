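Package: capcure
Title: Locus Curation and Gene-Tree Incongruence Tools for Target-Capture Phylogenomics
Version: 0.1.0
Authors@R: person("capcure", "developers", email = "capcure@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the locus-curation stages used in
    target-capture (hybrid-enrichment) phylogenomic studies: bait tiling with
    soft-mask filtering, replicate read-pair removal, k-mer based locus
    binning, reading-frame prediction with stop-codon trimming, intron
    splicing against bait exons, reciprocal-best-hit paralog screening,
    cross-contamination detection from per-locus p-distances between
    distantly related taxa, quartet-based treelikeness scoring for
    informative-locus selection, supermatrix concatenation with alignment
    statistics and partition files, and internode certainty (IC/ICA) with
    tree certainty (TC) computed from possibly partial gene trees. A
    synthetic-data generator plants duplicates, paralogs, introns and
    contamination events with truth tables so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
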
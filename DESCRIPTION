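Package: haloscan
Title: Composition, Codon-Usage and Replication-Skew Scans for Multi-Replicon Archaeal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sliding-window analyses of prokaryotic (especially haloarchaeal)
    replicons: synonymous codon usage tables and a moving-window chi-square scan
    that calls genomic islands of atypical codon usage, GC content and
    codon-position composition metrics, cumulative nucleotide-disparity (Z-curve)
    and windowed GC-skew tracks with replication-origin signal localization,
    Henderson-Hasselbalch isoelectric-point profiling of proteomes, a permutation
    test for the GC context of insertion-sequence elements, and median-offset
    calibration between legacy genetic-map coordinates and an assembly. Includes
    a seeded generator of annotated synthetic multi-replicon genomes so every
    detector can be verified against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    graphics,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
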
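Package: polyRT
Title: Sorting-Free Replication Timing Profiling of Polyploid Tissues from
    Read Depth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers replication timing (RT) profiles of polyploid tissues
    from whole-genome sequencing read depth, without cell sorting. Read
    depth is tallied in windows of a fixed number of uniquely alignable
    base pairs, corrected for GC bias, screened for underreplicated (UR)
    regions by penalized change-point segmentation, normalized against
    fully replicated chromosome arms so that UR copy-number loss is
    preserved rather than absorbed, smoothed with a cubic smoothing
    spline, and classified into genome-wide RT quartiles. Between-sample
    RT variants are called by windowed one-way ANOVA with Bonferroni
    control. A ground-truthed simulator of polyploid-tissue sequencing
    depth (S-phase copy-number gradient, underreplicated regions,
    GC-dependent coverage bias, count noise) makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
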
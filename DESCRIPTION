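Package: dnsatlas
Title: Differential MNase Sensitivity (DNS-seq) Chromatin Accessibility Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for differential micrococcal nuclease sensitivity
    (DNS-seq) analysis of large, repeat-rich plant genomes. Converts
    light- and heavy-digest MNase read intervals into per-million
    normalized 10-bp coverage tracks and DNS score tracks (light minus
    heavy), calls MNase hyper-sensitive (MSF) and hyper-resistant (MRF)
    footprints by genome-wide standardized-score segmentation with
    two-replicate consensus, situates footprints relative to genes,
    transposable elements and chromosome segments, profiles metagene and
    homoeolog-triplet accessibility in allopolyploids, models intergenic
    DNS decay, predicts centromeres from the joint DNS / Cereba-density /
    read-depth signature, and partitions phenotypic variance across
    chromatin-accessibility quintiles with a GRM + REML estimator. A
    synthetic allopolyploid genome generator with full ground truth makes
    every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
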
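Package: crsqtlkit
Title: Collapsed Rare-Variant Splicing QTL Discovery and Association Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds quality-controlled reference databases of candidate
    splice junctions from RNA-seq split-read evidence and outlier statistics,
    links rare DNA variants to those junctions through sequence-to-function
    splice predictions (SpliceAI and Pangolin annotation formats), collapses
    linked variants into crsQTLs (collapsed rare-variant splicing QTLs), and
    tests crsQTL and gene burdens for case-control association with Firth
    penalized logistic regression. Includes a seeded synthetic-cohort
    generator covering every input format, a dosage-usage linear regression,
    and a Poisson power calculator for junction detectability.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
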
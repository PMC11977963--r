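Package: splicescreen
Title: Splicing-Reporter, Lifespan and Drug-Microbe Screen Analytics for C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a C. elegans drug-microbe-host longevity
    study design: ratiometric GFP/mCherry splicing-reporter quantification
    with ROI-based background subtraction, genome-wide splicing-efficiency
    metrics (percent unannotated junction reads, percent intronic bases,
    cassette-exon PSI), Kaplan-Meier/log-rank lifespan statistics with
    worm-specific censoring, three-way bacterial-strain screen analytics
    (extension matrices, drug-dependence and rescue calls, OD600/CFU/growth
    summaries), and bacterial omics post-processing (per-feature t
    statistics, hypergeometric regulon enrichment, PLS-DA VIP scores). Every
    input can be simulated with known ground truth, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    rtracklayer,
    mixOmics,
    jsonlite,
    optparse
Config/testthat/edition: 3
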
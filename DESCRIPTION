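Package: selextrack
Title: Enrichment Analytics for In Vivo SELEX Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Informatics pipeline for in-vivo SELEX aptamer selections:
    FASTQ ingest with index demultiplexing and random-region extraction into
    counted sequence pools, round-by-round enrichment metrics (unique-sequence
    fractions, nucleotide composition, copy-number binning, pool overlap,
    fold-change trajectories), two-criterion candidate ranking with a
    tumour/kidney partition readout, a reproducible synthetic selection-campaign
    simulator with a selection-coefficient estimator, planar fluorescence-image
    ratio quantification with pooled-SD group comparison, and qPCR
    standard-curve quantification with single-stranded DNA library arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tiff,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
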
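Package: grcscan
Title: Detection and Characterization of a Germline-Restricted Chromosome
    from Paired Soma/Germline Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and characterizes a germline-restricted chromosome
    (GRC) from long-read sequencing of paired somatic and germline samples
    of the same individual. Implements per-site allele counting with depth
    filters, the windowed 'relspec' allele-specificity statistic with
    top-fraction window selection, extraction of germline reads carrying
    germline-specific variants, corrected-coverage copy-number estimation
    for candidate GRC regions, and comparison of GRC genes with their
    A-chromosome paralogs (architecture and expression). Includes a
    ground-truthed synthetic data generator emulating HiFi-like reads from
    soma and germline compartments for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
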
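Package: aqpscan
Title: Aquaporin Gene-Family Annotation and Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterization pipeline for plant aquaporin (MIP) gene families,
    built around the screening and annotation workflow used for Brassicaceae
    proteomes. Screens candidate proteomes for aquaporin-like proteins, detects
    NPA-motif variants and NPA-NPA spacing, extracts the ar/R selectivity filter
    (H2, H5, LE1, LE2 and the fifth Loop-C residue) and Froger positions by
    guided global alignment against annotated references, classifies proteins
    into the PIP/TIP/NIP/SIP subfamilies with genome-aware nomenclature, and
    predicts substrate specificity by rule. Expression utilities cover RPKM
    normalization, threshold-based expressed-gene and differential-expression
    calls, percentile-thresholded co-expression networks, average-linkage
    clustering and allopolyploid genome-dosage dependency tests. Synthetic-data
    generators emit aquaporin-like cohorts and expression matrices with
    machine-readable planted truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    methods,
    ape,
    rtracklayer,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    jsonlite
Config/testthat/edition: 3
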
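Package: resectquant
Title: Quantification of DNA End Resection from Strand-Specific
    Sequencing, qPCR Protection Assays and Fluctuation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify 5'-to-3' DNA end resection at a
    site-specific double-strand break (DSB). Implements strand-specific
    sequencing quantification (equal-depth read subsampling, per-strand
    coverage, division by the uninduced sample, binned windows around the
    DSB, selection of DSB-independent RPA reference peaks and
    peak-normalized RPA-ChIP enrichment profiles), single-stranded DNA
    quantification from restriction-protection qPCR, gene-conversion
    quantification from calibration curves, and Ma-Sandri-Sarkar
    maximum-likelihood estimation of recombination rates from
    Luria-Delbruck fluctuation assays. A synthetic-data generator
    emulates a resecting cell population with known ground truth so the
    whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
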
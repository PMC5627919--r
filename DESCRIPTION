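Package: barcodeforge
Title: High-Throughput COI Specimen Barcoding and Metabarcoding Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for recovering one mitochondrial COI barcode per
    specimen from multiplexed amplicon reads, with screening against
    prey/endosymbiont contamination and PCR chimeras; for building an
    indigenous reference barcode database audited with Kimura two-parameter
    (K2P) divergences and bootstrapped neighbor-joining trees; and for
    annotating community metabarcoding OTUs against one or more reference
    databases with identity and alignment-length thresholds. Includes a
    seeded synthetic-data generator that produces coding COI-like barcodes,
    specimen read sets with contamination and chimeras, and multi-sample
    communities with ground-truth manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
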
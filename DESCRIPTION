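Package: tfcrpipe
Title: Calling and Characterising Transcription-Factor Binding-Site
    Clustered Regions from Chromatin Accessibility Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies transcription-factor binding-site clustered
    regions (TFCRs) from motif hits in accessible chromatin by Gaussian
    kernel density estimation, scores their complexity (TC), width (TW),
    unit-base complexity (cw) and chromatin accessibility (CAS), links
    them to genes by nearest transcription start site, classifies links
    into proximal-to-long-range distance regions (R1-R4), tracks TFCR
    gain, loss and stability across developmental stages, clusters
    complexity trajectories with fuzzy c-means, and annotates TFCRs with
    TAD co-localisation and phase-separation-associated transcription
    factors. Ships a synthetic-data generator with known ground truth so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    e1071,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
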
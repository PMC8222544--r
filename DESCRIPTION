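Package: thresholdscape
Title: Threshold Cascades and Missed Associations in Untargeted LC/MS Peak Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how peak-height and detection-frequency thresholds
    shrink an untargeted LC/MS aligned peak table and how many
    phenotype-associated peaks they discard. Parses MS-DIAL style tab-delimited
    peak lists and alignment exports, applies the file- and alignment-level
    filter cascade (peak height, height-in-minimum-fraction-of-samples,
    post-gap-fill detection frequency, gap-fill intensity floor), summarises
    peak height and signal-to-noise distributions with quantile bins, runs a
    metabolome-wide Spearman scan with Benjamini-Hochberg adjustment, and
    intersects the significant set with the cascade masks to measure insight
    loss. Includes a synthetic-study generator with limit-of-detection
    censoring, gap filling and planted rank associations so the whole pipeline
    is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
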
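Package: migratic
Title: Microfluidic Migration-Chip Quantification and Tumor-Initiating Cell Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis stack for high-throughput microfluidic cell-migration
    assays used to functionally enrich tumor-initiating cells. Provides a
    seeded synthetic-image generator that emulates a 900-channel migration
    chip with ground truth; the automated per-channel quantification
    pipeline (TIFF import, channel segmentation, threshold-based cell
    calling, debris and dead-cell exclusion, migration-frontier distance);
    nonparametric assay statistics (Mann-Whitney U, box summaries,
    significance stars); limiting-dilution stem-cell-frequency estimation
    under the single-hit Poisson model with Wald confidence intervals; and
    cross-cell-line differential-expression prioritization with
    median-split Kaplan-Meier survival concordance screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    EBImage,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
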
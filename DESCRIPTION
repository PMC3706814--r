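Package: fameqc
Title: Quantification and Quality Control for GC-FID Fatty Acid Methyl Ester
    Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for high-throughput plasma phospholipid fatty acid
    profiling by gas chromatography with flame ionization detection.
    Implements retention-time-based identification of fatty acid methyl
    esters against a panel ladder, blank-corrected relative-percent (area
    percent) quantification with below-limit-of-quantification flagging,
    calibration linearity, signal-to-noise detection limits and spike
    recovery diagnostics, Shewhart control charting of internal quality
    control materials across batches with long-term precision statistics
    and summary-statistics one-way ANOVA, and manual-versus-automated
    method agreement analysis (Bland-Altman, correlation of means).
    Includes a seeded synthetic peak-table generator so the full pipeline
    is exercisable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
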
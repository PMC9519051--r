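Package: zfarrest
Title: Quantifying Tonic Immobility in Larval Zebrafish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for vibration-induced behavioural arrest (tonic
    immobility) in larval zebrafish: per-epoch swim speeds, the arrest statistic,
    censored half-recovery times and path-straightness measures from locomotor
    tracking; swim-bout segmentation and turn/forward classification from
    high-speed trajectories; startle and righting-reflex responsiveness;
    ratiometric calcium-imaging responder detection (LoG nucleus detection,
    frame registration, dR/R extraction, mean + 3 SD classification); masked
    pERK/tERK activity ratios; and transcript-enrichment statistics
    (median-of-ratios normalisation, rank-sum tests, Benjamini-Hochberg
    control). A bout-based locomotion and imaging simulator generates every
    input with known ground truth so the whole pipeline is testable without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr
Suggests:
    DESeq2,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
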
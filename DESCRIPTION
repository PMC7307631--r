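Package: pawtrigger
Title: Closed-Loop Markerless Paw-Movement Triggering and Validation
    Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation, streaming evaluation, and validation analytics for
    selective pose-based behavioral feedback in head-fixed mice. Provides a
    ground-truthed synthetic session generator (scripted forepaw reaches,
    grooming co-movements, frame drops, timestamp jitter, and a rendered
    feedback LED), paired-frame displacement triggering with contralateral
    suppression and a refractory period, a brute-force offline oracle for
    equivalence testing, mock feedback hardware, dual-route feedback-latency
    quantification (software time stamps versus LED-contrast ground truth),
    and the full trial-statistics pipeline: trigger-count tables, paired
    t-tests with Bonferroni correction, per-digit movement ANOVAs, and
    bootstrap estimation of mean differences with BCa confidence intervals.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
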
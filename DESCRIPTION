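Package: gaitwatts
Title: Rapid Energy-Expenditure Estimation from Ground Reaction Forces and EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven estimation of walking metabolic power (Watts) at the
    time scale of a single gait cycle or a fixed four-second window, from
    multichannel ground reaction force and electromyography recordings.
    Implements the standard biomechanics conditioning chains (zero-phase
    Butterworth filtering, EMG envelope extraction and normalization),
    heel-strike segmentation, per-cycle feature binning, Brockway indirect
    calorimetry ground truth, three estimator families (ordinary least
    squares, feedforward network, recurrent network), and the evaluation
    protocol for novel-condition, novel-subject and both-novel use cases,
    including mass-normalized error metrics and a pairwise
    condition-ordering statistic. A synthetic multi-subject walking-data
    generator with known ground truth makes the whole pipeline testable
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
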
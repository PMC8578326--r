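Package: lotra
Title: Local Topological Recurrence Analysis of Time-Series Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Un-thresholded recurrence analysis of dynamic signals. Phase-space
    trajectories are reconstructed by time-delay embedding (with data-driven
    delay and dimension selection via average mutual information and false
    nearest neighbours), and the pairwise Euclidean distance matrix is
    transformed cell-by-cell into 8-bit local-binary-pattern codes describing
    the inequality structure of each 3x3 neighbourhood. Code-band masks and
    classical epsilon-thresholded recurrence matrices feed a full set of
    recurrence quantification statistics (recurrence rate, determinism,
    diagonal-line entropy, laminarity, trapping time), which in turn drive a
    support-vector-machine classifier evaluated by nested leave-one-out
    cross-validation. Includes simulators (sine wave, Lorenz attractor, a
    synthetic digitised spiral-drawing cohort), readers for tablet
    spiral-drawing records, and photometry signal conditioning.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    e1071,
    deSolve,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
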
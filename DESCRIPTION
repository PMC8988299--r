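Package: spindlescore
Title: Sleep and Freezing State Scoring from Cortical Spindle-Band Power
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated scoring of rodent behavioral states from local field
    potentials (LFP) and a motion readout. Partitions immobility into
    slow-wave sleep, REM sleep, quiet wakefulness, and freezing using the
    smoothed cortical spindle-band (9-17 Hz) Hilbert envelope, which is high
    during slow-wave sleep but low during freezing, where the classical
    theta/delta ratio fails because the 4 Hz freezing rhythm overlaps the
    delta band. Includes the standard theta/delta scoring baseline for
    comparison, unsupervised 1-D thresholding (two-means and Otsu), interval
    algebra for behavioral epochs, Neuroscope-style flat-binary LFP I/O, a
    seeded synthetic session generator with ground truth, and a command-line
    entry point.
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
    optparse,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
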
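Package: pcsacc
Title: Purkinje Cell Simple- and Complex-Spike Analysis for Pro- and Anti-Saccade Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of cerebellar Purkinje cell recordings
    during randomly interleaved pro- and anti-saccade tasks. Provides a
    ground-truth synthetic session generator (trial schedules, minimum-jerk
    eye traces, inhomogeneous-Poisson simple/complex spike trains), adaptive
    velocity-threshold saccade detection and trial scoring, Gaussian-kernel
    spike density functions, Purkinje cell identification via the
    post-complex-spike pause, facilitation/suppression/ramping cell
    classification, population modulation metrics, complex-simple spike
    reciprocity with outlier-robust regression, and a from-scratch demixed
    principal component analysis with cross-validated stimulus decoding and
    shuffle-based significance testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
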
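Package: reachenc
Title: Kinematic Encoding Models for Intracranial Reaching Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fitting time-lagged ridge-regression encoding models that
    map reach kinematics onto high-frequency activity (HFA, 70-200 Hz) recorded
    from intracranial electrode grids during an instructed-delay reaching task.
    Includes a synthetic-session simulator with known ground-truth encoding
    filters, event-based trajectory reconstruction with beta-profile velocities,
    band-split Hilbert-envelope HFA extraction, nested cross-validated ridge
    fitting with within- and across-arm generalization, electrode-level tuning
    and generalization metrics (modulation depth, tuning similarity,
    generalization index, CC_norm), and permutation-based inference including
    cluster-based tests on time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    tibble,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
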
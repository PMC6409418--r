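Package: pathpos
Title: Path-Based Estimation of Clinical Trial Success Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs drug development paths from flat clinical-trial
    registry records and estimates probabilities of success (POS) for each
    clinical phase and for the full Phase 1-to-approval trajectory.
    Implements both the path-by-path estimator, which counts reconstructed
    development paths including imputed missing interior phases, and the
    classical phase-by-phase estimator based on directly observed phase
    transitions, together with binomial standard errors, rolling-window time
    series, subgroup analyses (therapeutic group, lead indication, biomarker
    use, orphan status, sponsor class, non-industry partners), completion
    rates and trial-duration summaries. A synthetic registry generator with
    known ground truth (per-phase advancement probabilities, right-censoring
    at a snapshot date, interior phase-record missingness) supports
    end-to-end validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
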
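Package: triageflow
Title: Digital Pediatric Triage Cascade, Outpatient Flow Simulation, and
    Time-to-Antibiotic Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a three-level (emergency/priority/non-urgent)
    pediatric triage cascade built from danger signs, a logistic
    admission-risk model, an additive respiratory-severity score, and
    age-banded vital-sign thresholds; a discrete-event simulator of a
    children's outpatient department under first-come-first-served versus
    triage-priority queue disciplines with imperfect prioritization
    adherence; and a quality-improvement evaluation pipeline for
    time-to-intravenous-antibiotic data: exclusion filtering, median
    comparisons with quantile-regression shift estimates, odds ratios,
    time-bracket distributions, a prioritization-adherence metric, and
    segmented quantile regression of the interrupted time series with
    counterfactual projection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    quantreg,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
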
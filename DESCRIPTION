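Package: relugc
Title: Event-Level Urinary Glucocorticoid Responses in Wild Primates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying the short-term glucocorticoid response to
    single behavioural events from non-invasively collected urine samples.
    Implements clearance-kinetics-based assignment of voided urine samples to
    pre-event and peak-excretion windows (with overlap-zone resolution),
    sample-level quality control (internal-standard recovery and creatinine
    thresholds), creatinine-corrected urinary glucocorticoid (uGC)
    summation, the event-level relative-uGC statistic, and Gaussian linear
    mixed models with a subject random intercept fitted by maximum
    likelihood with likelihood-ratio tests, collinearity and
    leave-one-subject-out stability diagnostics. Includes a forward
    simulator of glucocorticoid secretion, urinary excretion and bladder
    accumulation for end-to-end validation with known ground truth, and an
    embedded event-level dataset of relative uGC responses of nine wild
    adult male chimpanzees as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    car,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
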
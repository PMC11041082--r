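Package: platalloc
Title: Optimal Treatment Allocation in Platform Trials with Shared Controls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and analysis tools for platform trials comparing two
    experimental arms against a shared control when the second arm enters
    (and the first arm may leave) while the trial is ongoing.  Provides
    closed-form variances of period-stratified treatment-effect estimators,
    with and without non-concurrent controls; minmax-optimal allocation
    solvers for free, partially fixed and fully fixed period sizes,
    including unequal-variance (Neyman-type) and sum-of-variances variants;
    period-adjusted estimation and one-sided testing on patient-level data;
    and a vectorized Monte-Carlo engine for power and type-I-error
    operating characteristics under additive time trends.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    utils,
    stats,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
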
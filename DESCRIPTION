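Package: cdsavings
Title: Cohort Modelling of Persistent Conduct Disorder and the Economics
    of Parenting Programmes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-analytic Markov cohort model of the natural course
    of clinical childhood conduct disorder and its modification by
    evidence-based parenting programmes. Builds anchored piecewise-linear
    persistence trajectories, applies intervention scenarios defined by
    drop-out, effectiveness and recidivism, and converts the gap between
    the control and intervention trajectories into discounted sector-level
    cost savings, net present values, break-even years and return
    multiples from public-sector and societal perspectives. Includes the
    responder-proportion estimator that converts trial arm summary
    statistics (post-treatment Eyberg Child Behaviour Inventory intensity
    scores) into proportions of children in the clinical range, and
    seed-deterministic generators for synthetic crime-cost schedules and
    trial tables so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
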
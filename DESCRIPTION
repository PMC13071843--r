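Package: headsim
Title: Discrete Event Simulation and Economic Evaluation of Headache Care
    Pathways
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A discrete event simulation of diagnostic and management pathways
    for patients with headaches in a capacity-constrained specialist system,
    with a health-economic layer. Patients arrive in continuous time at
    primary care, may be referred to neurologists served by a finite
    first-come first-served waitlist during working hours, and move from not
    effectively managed to effectively managed care. The package compares the
    standard of care against adding an asynchronous eConsult triage step at
    referral, computing specialist-assessment wait times, discounted costs
    from societal or healthcare perspectives, quality-adjusted life-years, and
    (incremental) net monetary benefit. It includes arrival-rate calibration
    to an observed wait-time target, common-random-number paired replications,
    scenario and consent-rate threshold analyses, and analytically tractable
    toy-queue configurations for validation against Erlang-C results.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
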
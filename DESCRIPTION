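Package: tedqueue
Title: Queueing and Cost Models for Centralized Teleemergency Doctor Services
Version: 0.1.0
Authors@R: person("tedqueue", "maintainers", email = "tedqueue@example.org",
    role = c("aut", "cre"))
Description: Steady-state M/M/k analysis of a teleemergency-doctor (TED)
    office, including the overburdening statistic P(i > k), a capacity
    planner that sizes the number of doctors for a tolerated overburdening
    probability, an annual cost model comparing centralized and
    decentralized offices, a discrete-event simulation oracle, a synthetic
    call-log generator with an hour-of-day intensity profile, and
    call-log analysis utilities (exclusion filtering, rate estimation,
    goodness-of-fit for the Markov assumptions).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
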
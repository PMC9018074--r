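Package: ctboolnet
Title: Continuous-Time Stochastic Simulation and Omics Personalisation of
    Boolean Signalling Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Kinetic Monte-Carlo (Gillespie) simulation of Boolean
    signalling networks on their state transition graph, with per-node
    activation/inhibition rates, time-windowed and asymptotic phenotype
    probabilities, and an exact master-equation oracle for small models.
    Models are personalised to per-sample omics profiles (mutations and
    copy-number states as discrete node forcings, expression as
    continuous modulation of transition rates and initial conditions).
    Supports exhaustive single/double knock-out and gain-of-function
    screens, gradual in-silico drug inhibition with trajectory-mixture
    semantics, dose and combination grids, Bliss-independence synergy
    scoring, and genetic-interaction (epistasis) analysis under four
    null models. Parsers and writers for BoolNet-style rule tables and a
    MaBoSS-style .bnd/.cfg dialect are included, plus generators for toy
    models with closed-form dynamics and synthetic omics cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
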
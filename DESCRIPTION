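Package: sprintergetics
Title: Bioenergetic Modelling of Sprint Running
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to estimate instantaneous metabolic power from sprint
    velocity profiles via the equivalent-slope energy cost of accelerated
    running, to decompose that power into aerobic, anaerobic-lactic and
    anaerobic-alactic contributions, to estimate maximal anaerobic
    capacities from a set of race performances, and to simulate minimal
    race times from capacities with an inverse power-to-kinematics
    algorithm. Includes fitting of the exponential sprint acceleration
    model to split tables, duration-dependent anaerobic energy
    availability models, and a synthetic split-table generator for
    testing and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
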
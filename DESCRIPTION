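Package: fcdnet
Title: Energy-Based Flowing Network Models and Their Evolution Under
    Systemic and Greedy Goal Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and analysing flowing connected directed
    networks (FCDNs): row-normalized weighted digraphs with a single
    energy input and a single dissipative output, used as toy models of
    open ecological systems.  Provides steady-state throughflow and flux
    computation via the Leontief inverse, pulsed and scarcity dynamics,
    the energy-flux decay rate, the classical systemic indexes of
    ecological network analysis (total system throughflow, average
    mutual information, ascendency, entropy difference, Finn cycling
    index), directed simple-cycle counting, hill-climbing network
    evolution at large and short time-scales under systemic or greedy
    goal functions, and an experiment driver that compares paired
    control and greedy evolutionary branches on scarcity tolerance and
    goal performance.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
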
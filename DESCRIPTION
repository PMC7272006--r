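Package: reactodx
Title: Disease Evolution and Probabilistic Diagnosis in Stochastic Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for modelling disease development as degradation of a
    stochastic chemical reaction network. Simulates population ensembles of
    mass-action networks with the Gillespie stochastic simulation algorithm,
    optimizes reaction rates towards a healthy state of maximal
    signal-to-response mutual information, degrades the network with a
    reverse simulated-annealing defect dynamics, and quantifies the
    time-dependent accuracy of a naive-Bayes style single-defect diagnosis
    together with an optimal intervention time.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    deSolve,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
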
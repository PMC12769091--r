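Package: templimits
Title: Thermodynamic Accuracy Limits of Molecular Templating Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing thermodynamic limits on copying accuracy in
    chemostatted linear molecular templating networks. Networks of complexes
    (a null complex, intermediates and products) connected by reversible
    mass-action reactions are represented as graphs obeying local detailed
    balance. The package enumerates self-avoiding assembly pathways and their
    free-energy changes, derives rigorous upper and lower bounds on
    steady-state species concentrations, evaluates closed-form bounds on
    single-product specificity and on the Shannon entropy of the product
    ensemble, solves deterministic steady states and transients, accounts for
    edge fluxes and entropy production, diagnoses pseudo-equilibrium versus
    cyclic-flux operation, and runs exact stochastic (Gillespie) simulations
    with trajectory-level production/degradation classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    igraph,
    deSolve,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
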
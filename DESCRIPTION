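Package: bondgraphr
Title: Modular, Thermodynamically Consistent Bond-Graph Modelling of
    Biochemical Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building biochemical reaction network models as bond
    graphs: energy-conserving species, reaction and junction components are
    composed hierarchically into modules, flattened, and converted into
    stoichiometric ODE systems with interchangeable thermodynamically
    consistent rate laws (Marcelin-de Donder mass action, reversible
    Michaelis-Menten, generalised/convenience kinetics).  Includes exact
    conserved-moiety and pathway analysis, kinetic/thermodynamic parameter
    conversion with detailed-balance (Wegscheider) checking, steady-state and
    perturbation benchmarking, pathway energetics, and built-in model
    generators for a MAPK signalling cascade (with positive and negative
    feedback variants) and the glycolysis pathway.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
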
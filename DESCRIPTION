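Package: coroperf
Title: Closed-Loop Cardiac-Coronary Simulation of Transmural Perfusion and
    Myocardial Work
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A closed-loop cardiovascular simulator coupling a five-compartment
    lumped-parameter systemic circulation, a transmurally resolved
    thick-walled-shell model of left-ventricular mechanics, and four nonlinear
    coronary microvascular Windkessel networks placed at different depths in
    the ventricular wall. Predicts transmural distributions of intramyocardial
    pressure, passive coronary perfusion, myofiber work density, and the work
    density-perfusion mismatch ratio under changes in contractility, preload,
    afterload, wall thickness, and cavity volume. Includes a seeded synthetic
    coronary-tree generator, sweep drivers with load-holding constraints, and
    a baseline calibration routine.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
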
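Package: compasscourse
Title: Compass-Course Simulation and Performance of Naive Animal Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and assessing compass-based migration of
    naive (first-time) animal migrants on a sphere. Implements five
    compass-course heading rules (geographic and geomagnetic loxodromes,
    magnetoclinic courses, fixed sun-compass and time-compensated
    sun-compass courses with three clock-handling variants), von Mises
    circular-error primitives, a stochastic population migration simulator
    with biologically structured orientation errors (cue detection,
    transfer, in-flight maintenance, autocorrelated drift and
    between-individual variability), analytic sensitivity of successive
    headings with a finite-difference oracle, and an analytic performance
    model fitted by nonlinear least squares with AICc model selection.
    Ships parameter sets for nine migratory species and a generic-migrant
    scenario generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
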
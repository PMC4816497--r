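Package: cardioib
Title: Immersed Boundary-Finite Element Simulation of Left Ventricular Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale fluid-structure interaction simulator for left
    ventricular (LV) mechanics based on the immersed boundary (IB) method
    with a finite element (FE) description of the myocardium. Implements
    the Holzapfel-Ogden orthotropic hyperelastic passive response with
    modified (tension-only) fibre invariants and a volumetric penalty, a
    length- and velocity-dependent active tension model driven by a
    prescribed calcium transient, rule-based fibre and sheet architecture
    on an idealized truncated-ellipsoid LV, infarct heterogeneity with a
    linear border zone, diastolic inflation and systolic activation
    protocols, bisection-based parameter estimation against cavity volume
    targets, and regional strain, stress, and rotation post-processing.
    The Eulerian solver is an explicit projection method for the
    incompressible Navier-Stokes equations on a staggered MAC grid,
    coupled to the Lagrangian FE mesh through a four-point regularized
    delta function.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
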
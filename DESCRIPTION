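Package: dllmc
Title: Dynamic Lattice Liquid Monte Carlo for Crowded Two-Dimensional
    Dimer-Solvent Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Cooperative-motion Monte Carlo simulation of a fully occupied
    two-dimensional triangular lattice containing solvent monomers, rigid
    dimers and immobile obstacles, using the dynamic lattice liquid (DLL)
    algorithm: per-step random direction fields, closed cooperative
    displacement loops (length three or more), excluded-volume and rigid-bond
    constraint validation, and synchronous execution.  Includes the standard
    dynamical-heterogeneity observables (mean square displacement, anomalous
    diffusion exponent, short- and long-time diffusion coefficients,
    non-Gaussian parameter, dimer end-to-end and solvent position
    autocorrelation functions, trapped fractions, cooperative-loop
    statistics), diffusion-coefficient fitting with an alpha-exponent gate,
    and a site-percolation estimator for obstacle matrices based on
    union-find wrapping detection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
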
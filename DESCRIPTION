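Package: cdc42sim
Title: Reaction-Diffusion Simulation of Cdc42 Polarization on the Fission
    Yeast Cell Surface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the GTPase cycle of Cdc42 on a closed spherocylinder
    membrane representing a fission yeast cell. Six coupled fields
    (Cdc42-GDP, Cdc42-GTP, a tip-localized GAP, fast and slow forms of a
    side-localized GAP, and a quasi-statically equilibrated conserved GEF
    pool) evolve by surface diffusion and reaction kinetics on a Voronoi
    discretization of the membrane. Includes a discrete Laplace-Beltrami
    operator on a quasi-uniform surface mesh, a forward-Euler integrator
    with stochastic activation noise, analysis tools that classify the
    emergent dynamical states (monopolar/bipolar, stationary/oscillatory,
    patch/wave), concentration profiles and exponential decay-length fits,
    and drivers for parameter-space scans and the cell-length series that
    reproduces the new-end take-off (NETO) transition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
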
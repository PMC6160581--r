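Package: coshnet
Title: Capillary Network Oxygen Transport and Outflow Saturation Heterogeneity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of oxygen transport in cortical capillary
    networks. Reconstructs blood flow from sparse red-blood-cell velocity
    measurements by hydraulic-power minimization, propagates hemoglobin
    saturation through the network with a Hill-equilibrium differential
    equation model, runs a reduced Lagrangian moving red-blood-cell surrogate
    with tissue compartments and diffusive interaction, computes geometric and
    functional supplied tissue territories, and quantifies capillary outflow
    saturation heterogeneity (COSH) against transit-time heterogeneity (CTH).
    Includes a seeded synthetic network generator that emulates the topology
    and flow statistics of reconstructed mouse somatosensory cortex networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
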
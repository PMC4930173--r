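Package: coguide
Title: Collective Guidance Models of Cluster Chemotaxis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Stochastic particle simulations and analysis tools for collective
    guidance: chemotaxis of cell clusters whose individual cells sense only the
    local chemoattractant level, not its gradient. Cells carry an
    Ornstein-Uhlenbeck polarity, repolarize away from contacts (contact
    inhibition of locomotion) with a susceptibility set by the local signal,
    optionally process the signal through a local-excitation global-inhibition
    (LEGI) network with finite intercellular diffusion and switchlike
    amplification, and may cohere through co-attraction to a secreted,
    screened chemoattractant field. The package provides an Euler-Maruyama
    integrator for the coupled dynamics, a rigid-cluster steady-state
    predictor of cluster velocity and chemotactic index, cluster-level
    observables (velocity, chemotactic index, angular speed, fragmentation,
    chirality-drift coupling), a reduced model of the rotation bifurcation
    with a pitchfork fitter, and a deterministic pair-scattering analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    deSolve,
    jsonlite,
    yaml,
    readr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
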
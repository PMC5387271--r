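Package: kinpipe
Title: Pipelines for Repeated Kinetic Model Simulation and Parameter
    Estimation with Sampled Profile Likelihood
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automates repetitive simulation and calibration tasks for
    mass-action kinetic models. Provides deterministic (ODE) and exact
    stochastic (Gillespie) simulators behind a uniform interface, an
    external-program wrapper protocol based on tab-separated report
    files, particle swarm parameter estimation with full evaluation
    tracing, sampled profile-likelihood confidence intervals with
    practical-identifiability classification, parameter correlation
    analysis, stochastic-ensemble summary statistics, single and double
    parameter scans, and YAML-configured pipelines that chain data
    generation, analysis and LaTeX/Markdown report generation.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    yaml,
    jsonlite,
    Matrix,
    parallel,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
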
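Package: gbfront
Title: Flux-Limited Modeling of the Glioblastoma Invasion Front
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates a one-dimensional five-species model of the
    glioblastoma invasion front: tumor density driven by flux-saturated
    (flux-limited) diffusion with saturated chemotaxis and haptotaxis,
    matrix metalloprotease (MMP1) production localized on the tumor
    microtube band, dynamic extracellular-matrix degradation, and
    active/inactive integrin kinetics with front-directed transport.
    Provides an IMEX time stepper (implicit tridiagonal transport solves,
    classical Runge-Kutta for the kinetic species) under no-flux boundary
    conditions, scenario builders for porosity-dependent propagation speed
    and chemosensitivity-driven front splitting, front-pattern metrics
    (front position, speed, width, peak shifts, component counts), and a
    synthetic confocal line-scan pipeline with penalized-least-squares
    smoothing and peak-ordering statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
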
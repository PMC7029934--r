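Package: eelpass
Title: Agent-Based Simulation of Juvenile Eel Passage Through Studded Eel
    Tiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the upstream ascent of juvenile European eels
    (elvers) through studded eel-tile fish passes. Provides a data model
    and delimited-text I/O for gridded near-bed velocity and depth fields,
    a parametric generator of CFD-like flow fields through a dual-density
    stud array, threshold classification of fields into passable,
    impassable and boundary cells with connectivity analysis, a lognormal
    burst-swimming-speed model fitted from published quantiles, cellular
    automata (CA) and individual-based (IBM) movement models with stuck
    detection, fall-back behaviour and a 20 s burst-endurance budget,
    passage-efficiency statistics, maximum-pass-length extrapolation and
    design-chart construction for pass installation angle, unit discharge
    and elver length.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    interp,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
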
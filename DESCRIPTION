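Package: genarith
Title: Genotype Arithmetic for Power-Law Regulatory Cascades
Version: 0.1.0
Authors@R:
    person("Sam", "Ortiz", email = "sortiz.dev@posteo.net", role = c("aut", "cre"))
Description: Models end-product-inhibition regulatory cascades in the S-system
    (power-law) formalism and predicts unknown kinetic orders, interpreted as
    numbers of binding sites, from the combinatorial geometry of the exponent
    space.  Provides cascade builders, exact log-linear steady-state solvers,
    local stability classification and time-course simulation; lattice-cone
    construction from monomial exponent vectors; a native Hilbert-basis engine
    for pointed rational cones (double description, saturated-lattice
    reduction, pulling triangulation, fundamental-parallelepiped enumeration)
    with Normaliz plain-format file interchange; torus fixed-point constraint
    systems over the unknown order and their admissible ranges in exact
    rational arithmetic; doubly stochastic aggregation of monoid generators;
    and a command-line interface for prediction, simulation and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
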
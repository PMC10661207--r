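Package: azokin
Title: Kinetic Simulation of Azo Dye Decoloration by a Fungal-Bacterial Consortium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the batch decoloration of the azo dye Acid Red 27 and the
    degradation of its aromatic metabolites by a microbial consortium of the
    white-rot fungus Trametes versicolor and the bacterium Pseudomonas putida.
    The model couples Monod fungal growth, diauxic Monod plus Haldane-Andrews
    bacterial growth, laccase production and decay, Michaelis-Menten enzymatic
    decoloration and first-order metabolite formation into six ordinary
    differential equations, integrated with a fixed-step fourth-order
    Runge-Kutta scheme and a discrete bacterial-inoculation event. Includes a
    three-level full-factorial scenario runner over initial glucose, initial
    dye and inoculation day, and quadratic response-surface (RSM) fits with
    grid-search identification of the locally optimal operating conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
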
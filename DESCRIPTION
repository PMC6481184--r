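Package: pumpleak
Title: Whole-Cell Pump-Leak Modelling of Monovalent Ion and Water Balance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the balance of Na+, K+ and Cl- fluxes, cell water
    volume and membrane potential in animal cells using the classical
    pump-leak framework: Goldman-Hodgkin-Katz electrodiffusion through
    integral Na+, K+ and Cl- channel permeabilities, a Na+/K+ pump with a
    first-order (optionally linearly decaying) rate coefficient, and
    electroneutral NC, KC and NKCC cotransporters. Membrane potential is
    obtained at every instant from macroscopic electroneutrality of the net
    charge flux and cell volume from osmotic balance with the medium.
    Includes utilities to convert raw measurements (buoyant density,
    ouabain-sensitive Rb+ influx, ion content per gram protein) into model
    inputs, a parameter-fitting workflow against observed ion time courses
    with an OSOR plausibility filter, sensitivity scans, plain-text
    parameter-file I/O, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
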
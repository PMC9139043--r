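Package: eiscap
Title: Capacitive Modeling of Nanoparticle-Decorated EISCAP Field-Effect Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates electrolyte-insulator-semiconductor capacitors (EISCAPs)
    whose gate surface is partially covered by charged, ligand-stabilized
    nanoparticles acting as nanometer-sized local gates. Implements the
    two-region (particle-covered / particle-free) depletion-approximation
    capacitance model, assembles full capacitance-voltage (C-V) curves across
    accumulation, depletion and inversion, solves the constant-capacitance
    (ConCap) readout condition for the gate-voltage shift induced by the
    particle layer, inverts observed shifts back to interfacial potential
    changes, and generates synthetic hard-disk particle placements by random
    sequential adsorption to emulate SEM-derived surface coverages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
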
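Package: biotft
Title: Decoupled Analysis of Protein-Interlayer Organic Transistor Biosensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing organic thin-film transistor (OTFT) biosensors
    that embed a layer of biotin-binding proteins (avidin, streptavidin,
    neutravidin) at the dielectric/semiconductor interface. Extracts threshold
    voltage and field-effect mobility from saturation-regime transfer curves,
    decouples the normalized binding-induced current response into an
    electrostatic (threshold-voltage) term and a conformational (mobility)
    term, and bridges the device track to a structural track: per-monomer
    electric dipole moments from partial charges, the Helmholtz dipole-layer
    threshold-voltage shift, the Debye dipole/induced-dipole interaction
    cutoff, and RMSD/RMSF fluctuation analysis of binding-pocket loops over
    trajectories. Includes seeded synthetic generators (transfer curves with
    noise, leakage and contact roll-off; bead-model tetramers with prescribed
    dipoles; harmonic-wobble trajectories) so every estimator can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
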
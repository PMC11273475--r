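Package: mihsim
Title: Magnetic Induction Hyperthermia Simulation on a Voxel Mouse Phantom
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end desk-scale simulation of magnetic-nanoparticle
    induction hyperthermia for a murine scalp melanoma. Computes the
    magnetic field of a distributed-winding Helmholtz coil pair by
    Biot-Savart superposition (on-axis and off-axis via complete elliptic
    integrals), converts the local field strength into a volumetric heat
    source with the Rosensweig superparamagnetic relaxation-loss model
    (Langevin equilibrium susceptibility, Neel/Brownian effective
    relaxation time), provides quasi-static induced electric field and
    current-density exposure estimates, and solves the Pennes bioheat
    equation by an implicit finite-volume scheme on a layered
    scalp/skull/brain voxel phantom carrying a nanofluid-loaded tumor.
    Reports temperature probe curves, per-region extrema and thermal-dose
    coverage fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
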
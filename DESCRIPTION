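Package: mschem
Title: Multiscale, Theory-Agnostic Molecular Modelling Driver
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A driver for common computational-chemistry job types (geometry
    optimization, surface scans, transition-state and minimum-energy crossing
    point searches, nudged elastic band, numerical Hessians with rigid-rotor
    harmonic-oscillator and quasi-RRHO thermochemistry, Wigner sampling, and
    Born-Oppenheimer molecular dynamics) that is strictly separated from the
    Hamiltonian. Any object implementing the uniform theory contract (energy,
    gradient, optional dipole and point-charge gradient) can drive every job.
    Ships built-in analytic potentials (a harmonic force field, an
    embedding-capable Morse/Coulomb surrogate for a quantum-chemistry code, and
    standard 2D test surfaces) plus full hybrid-theory machinery: additive
    QM/MM with link atoms, charge shifting, redistributed charge and dipole
    (RCD) boundaries and link-force projection; subtractive 2- and 3-layer
    ONIOM; and additive theory composition (WrapTheory).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
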
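Package: radscav
Title: Thermodynamic Descriptors, Mechanism Classification and TST
    Kinetics for Radical-Scavenging Antioxidants
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing pipeline for quantum-chemistry thermochemistry
    of phenolic antioxidants. Computes the five descriptors of the three
    canonical radical-scavenging routes (bond dissociation enthalpy,
    ionisation potential, proton dissociation enthalpy, proton affinity,
    electron transfer enthalpy) from per-species enthalpies, validates
    descriptor tables through their Hess-cycle identities, classifies the
    thermodynamically preferred mechanism (HAT, SET-PT or SPLET) per
    compound and phase, analyses double hydrogen-atom-transfer product
    channels, assembles reaction potential-energy-surface profiles, and
    evaluates conventional transition-state-theory rate constants with the
    Wigner tunnelling correction. Ships reference tables for the five
    grape-skin anthocyanin-3-O-glucosides and a synthetic enthalpy
    generator that inverts the descriptor equations for offline testing.
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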
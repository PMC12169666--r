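Package: ronsff
Title: GROMOS-Compatible Force Field Toolkit for Reactive Oxygen and
    Nitrogen Species
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Parameter database, energy model and analysis tools for a
    united-atom GROMOS-type force field covering fifteen reactive oxygen
    and nitrogen species (RONS): H2O2, O2, HO2, HO, O3, N2O4, NO2, NO,
    HOONO, HNO3, HNO2 and the NO3-, NO2-, O2- and ONOO- anions.  Provides
    validated machine-readable parameter tables with multi-slot C12
    Lennard-Jones combination rules, gas-phase potential-energy evaluation
    with GROMOS exclusion and third-neighbor (1-4) handling, rigid-bond
    conformer minimization and torsional scans, thermodynamic-integration
    quadrature and conformer-weighted hydration free energies, a
    GROMACS-dialect topology emitter/reader, and radial-distribution and
    ion-pairing trajectory analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
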
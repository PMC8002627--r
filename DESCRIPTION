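Package: crebind
Title: Conformer-Rotamer Ensemble Binding Free-Energy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for host-guest binding free-energy analysis from
    conformer-rotamer ensembles (CREs): multi-frame XYZ ensemble I/O with
    comment-line energies, Kabsch superposition RMSD and rotational
    constants, duplicate/rotamer/conformer classification with energy-window
    pruning, rigid-rotor harmonic-oscillator thermochemistry, Boltzmann
    ensemble averaging with conformational entropy, three flavors of
    ensemble binding free energy, benchmark deviation statistics against
    experimental reference tables, and a seeded toy torsional-molecule
    generator with RMSD-biased metadynamics sampling and a brute-force
    grid oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
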
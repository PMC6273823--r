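Package: cdftkit
Title: Conceptual-DFT Reactivity Analysis for Michael-Acceptor Curcuminoids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-processing toolkit for conceptual density-functional-theory
    reactivity analysis of alpha,beta-unsaturated ketone electrophiles, built
    around N-substituted 4-piperidone curcumin analogues. Computes global
    reactivity indices (electronic chemical potential, hardness,
    electrophilicity) from frontier-orbital energies; adiabatic and vertical
    electron affinities and vertical detachment energies from neutral/anion
    energy quadruples with zero-point and composite-basis bookkeeping;
    Mulliken atomic populations, condensed Fukui f+ and Parr P+ site
    indices, and fragment-resolved molecular-orbital composition with
    valence- versus dipole-bound anion classification; Hammett sigma
    linear free-energy correlations; and rigid two-dihedral torsional grid
    scans with a pluggable energy callback. Ships synthetic-record
    generators that invert each analysis stage for exact ground truth, plus
    packaged reference tables, so the whole pipeline is exercisable without
    any quantum-chemistry run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
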
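Package: gelforge
Title: Rational Design Toolkit for Cyclodextrin-Functionalized Crosslinked
    PVA Hydrogels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for the in-silico design and experimental
    statistics of gamma-cyclodextrin-functionalized crosslinked polyvinyl
    alcohol hydrogels used as drug-release platforms. Covers molecular
    structure handling (XYZ/PDB input and output, formula arithmetic,
    idealized polymer builders), rigid-body host-guest orientation screening
    with supermolecular interaction energies under a pluggable
    Lennard-Jones/Coulomb energy model, stoichiometric crosslinked-network
    construction with cyclodextrin grafting and guest placement, structural
    observables over coordinate frames (radius of gyration, solvent
    accessible surface area, water and guest capture counting, hydrogen
    bonds), and the factorial-design statistics of swelling and drug
    release (factor coding, standardized-effect screening, reduced-model
    regression, cumulative release with aliquot correction). Every input
    class can be generated synthetically with known ground truth.
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
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
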
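Package: wrapmap
Title: Lattice-Wrapping Geometry and Motor-Gating Analysis for
    Microtubule-Associated Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative toolkit for microtubule-associated proteins (MAPs)
    that bind the microtubule lattice circumferentially through periodic
    pseudo-repeats. Detects degenerate PhiXXWXXXK binding repeats in protein
    sequences and derives their spacer statistics; models the wrap geometry of
    an alpha-helical MT-binding domain across protofilaments; computes
    inter-protein C-alpha cross-correlation maps from multi-run molecular
    dynamics trajectories and classifies residue-residue contacts (salt
    bridges, hydrogen bonds, hydrophobic and repulsive pairs) with per-run
    occupancy fractions; estimates single-molecule motility statistics (run
    frequency, run length, velocity) and equilibrium binding affinity by
    Langmuir-isotherm fitting; and segments microtubule tip traces into
    growth, shrinkage and pause phases to estimate growth rate, catastrophe
    frequency and depolymerization rate. Seeded synthetic-data generators
    emulate every input so each stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    MASS,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
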
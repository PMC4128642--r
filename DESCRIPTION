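Package: aquaflux
Title: Osmotic Water Permeability Kinetics and Aquaporin Sequence Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing aquaporin water channels expressed in
    yeast. Estimates osmotic water permeability (Pf) from stopped-flow
    fluorescence relaxations via a two-compartment osmometer model and
    single-exponential fitting, Arrhenius activation energies (Ea) across a
    temperature series, and mercurial inhibition with Student's t statistics.
    Annotates aquaporin protein sequences: NPA and regulatory motifs, the
    aromatic/arginine (ar/R) selectivity filter and P1-P5 residues with
    rule-based prediction of atypical-substrate transport, Kyte-Doolittle
    hydropathy segments, pairwise identity, p-distance matrices and
    neighbor-joining trees. Includes synthetic generators for traces,
    temperature series and aquaporin-like sequences with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    ape,
    jsonlite,
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
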
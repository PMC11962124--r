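Package: propro
Title: Modelling and Quantification of PLK1-Inhibited Mitotic Entry
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how inhibition of polo-like kinase 1 (PLK1)
    delays mitotic entry. Implements a bistable ordinary-differential-equation
    model of the cdk1-cyclin B activation network extended with a PLK1 term
    acting on the cdc25 phosphatase, single-cell simulation of nuclear
    envelope breakdown (NEBD) timing, population simulations over
    heterogeneous cdk2-cyclin A activities with cumulative-entry summaries,
    and numerical steady-state and saddle-node analysis of the network.
    Also provides the quantification metrics used on live-cell label movies
    (chromosome-condensation score, nuclear-to-cytoplasmic ratio, FRET
    ratio, eccentricity, z-centroid, focus counting, cumulative NEBD), and a
    phosphoproteomics statistics pipeline for 2x2 factorial TMT designs:
    site filtering, missing-not-at-random imputation, per-batch median-polish
    normalisation, moderated t statistics with empirical-Bayes variance
    shrinkage, interaction and pairwise contrasts, and hit classification.
    Seeded synthetic-data generators make every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    limma,
    tiff,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
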
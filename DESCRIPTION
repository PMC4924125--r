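Package: sdri
Title: Ranking Structure-Determining Residues from Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks every residue (or nucleotide) of a macromolecular
    structure by a structure-determining residue identifier (SDRI): the
    node's dynamical Shannon entropy in a Markov-chain model of the
    frame-averaged residue interaction network, divided by its root mean
    square fluctuation across the conformational ensemble. Reads
    multi-model PDB ensembles (NMR models or molecular-dynamics frames),
    builds van der Waals-normalized center-of-mass distance networks,
    computes stationary distributions and per-node entropies, contact
    grades, min-max normalized scores, ranks, the complementary
    per-residue disorder profile, and distribution statistics. Also fits
    two-state thermal unfolding curves and evaluates mutant stability
    differences (delta-delta-G) for thermal and chemical denaturation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    e1071,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
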
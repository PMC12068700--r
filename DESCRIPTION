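Package: resphylo
Title: Relative Evolutionary Scoring and Phylogenetic Screening of
    Lifespan-Associated Residues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies per-residue evolutionary change in a protein
    multiple sequence alignment as position-specific log-odds scores
    (relative evolutionary scores, RES) and screens each alignment column
    for association with a continuous species trait such as average
    lifespan using phylogenetic generalized least squares under a
    Brownian-motion covariance. Includes maximum-likelihood estimation of
    Pagel's lambda, neighbor-joining tree construction from p-distances,
    max-to-average lifespan normalization, mapping of significant columns
    onto a reference ortholog, and a fully seeded synthetic-data generator
    (Yule trees, Brownian traits, trait-linked alignments) for power and
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    grDevices,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    nlme,
    phangorn,
    phytools,
    optparse,
    pheatmap
Config/testthat/edition: 3
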
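Package: ontomorph
Title: Ontogenetic Geometric Morphometrics and Heterochrony on Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying cranial ontogeny and heterochrony with
    two-dimensional landmark data. Provides generalized Procrustes
    superimposition (semilandmarks weighted as landmarks, no sliding),
    principal component ordination with broken-stick component selection,
    multivariate regression of shape on log centroid size with permutation
    tests and regression scores, stratigraphic time calibration of
    supertrees, squared-change parsimony ancestral shape reconstruction,
    permutation and multivariate-K tests of phylogenetic signal,
    quantification of two-stage ontogenetic trajectories (angles, lengths,
    slopes), and classification of ancestor-descendant shape changes as
    paedomorphic or peramorphic. Includes a seed-deterministic synthetic
    data generator emulating allometric growth, Brownian evolution of
    adult shapes and injected heterochronic shifts, plus readers and
    writers for TPS, CSV, MorphoJ text exports and NEXUS/Newick trees.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
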
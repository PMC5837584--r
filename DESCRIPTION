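Package: probdist
Title: Probabilistic Distances Between Phylogenetic Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes Hellinger, Kullback-Leibler, Jensen-Shannon and
    total-variation distances between phylogenetic trees regarded as
    probability models on sequence characters. A tree together with its
    substitution model (two-state symmetric, or GTR with discrete-Gamma
    rate heterogeneity and optional invariant sites) induces a
    distribution on site patterns at the leaves; distances between two
    such distributions are computed exactly by enumeration for small
    taxon sets and otherwise estimated by Monte Carlo simulation with
    principled sample-size planning from a pilot run. Trees with
    differing taxon sets are compared by restriction to the common taxa
    or by uniform augmentation to the taxon union. Includes random tree
    generators (Yule topologies, Gamma edge lengths, SPR perturbations),
    pairwise distance matrices with classical multidimensional scaling,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
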
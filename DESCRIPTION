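Package: phylocoev
Title: Coevolution Analysis of Presence-Absence Patterns on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects coevolving binary characters (gene families, introns,
    restriction sites) from phyletic patterns. Fits two-state gain/loss
    continuous-time Markov models with among-character rate variation
    (gamma plus invariant, or independent gain/loss rate mixtures) by
    maximum likelihood with an optional correction for unobservable
    all-absent characters, maps posterior expected gain and loss events
    onto branches by analytic stochastic mapping, scores co-occurrence of
    mapped events between character pairs, assigns significance by
    parametric simulation with abundance-matched null strata and
    Benjamini-Hochberg false discovery rate control, and exports the
    resulting coevolution network. Includes neighbor-joining tree
    estimation from maximum-likelihood two-state distances and a
    simulation benchmark comparing phylogeny-aware detection with
    correlation of extant patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
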
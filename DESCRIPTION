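Package: habitevol
Title: Ancestral State Reconstruction and Convergence Analysis for
    Categorical Life-Habit Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the evolutionary history of a categorical
    life-habit character on a rooted phylogeny and asks how often, and
    along which trajectories, derived habits arose.  Implements the
    single-rate Markov k-state (Mk1) likelihood with marginal ancestral
    state reconstruction and a log-likelihood decision rule, unit-cost
    (Fitch/Sankoff) parsimony with full most-parsimonious-reconstruction
    sets, enumeration of ancestor-to-descendant state transitions,
    classification of repeated origins as parallel or convergent, and a
    chi-square test for bias in which states act as evolutionary
    progenitors.  A pure-birth tree simulator and an event-level Markov
    character simulator with recorded change histories make every stage
    testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    phangorn,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
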
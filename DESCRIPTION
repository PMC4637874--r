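Package: phyloconverge
Title: Detection of Molecular Convergence by Sitewise Likelihood Support and
    Codon Model Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and characterizing molecular convergence in
    independently evolved lineages. Implements sitewise log-likelihood support
    (SSLS) comparisons between a species tree and alternative topologies that
    force focal lineages into a monophyletic clade, with significance assigned
    from a simulation-based empirical null distribution; empirical Bayes
    marginal ancestral sequence reconstruction and classification of amino
    acid substitutions into parallel, unique and backward categories; codon
    substitution models (one-ratio, branch, branch-site, M7/M8 and Clade
    Model C) with likelihood-ratio tests for rapidly evolving and positively
    selected genes; locus-wise regressions linking sitewise convergence
    support to sitewise selection pressure; and a sequence-evolution
    simulator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    seqinr,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
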
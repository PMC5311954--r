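Package: msapBF
Title: MS-AFLP Methylation Profiling and Bayesian Log-Linear Association
    Analysis for Noninfectious Bud Failure in Almond
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing methylation-sensitive amplified fragment
    length polymorphism (MS-AFLP/MSAP) band matrices from paired HpaII/MspI
    isoschizomer assays: reading and validating presence/absence band
    matrices, four-state methylation epigenotype calling, partition of
    methylation-susceptible loci, concordance (Kendall tau-b) and
    independence statistics on contingency tables, principal coordinates
    ordination and UPGMA dendrograms, and Bayesian hierarchical log-linear
    model selection on contingency structures by reversible-jump MCMC under
    a generalized hyper-g prior, with posterior predictive model checking.
    Includes a synthetic band-matrix generator emulating a 22-accession
    almond noninfectious bud-failure study design so every pipeline stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
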